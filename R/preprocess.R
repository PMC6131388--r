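## Preprocessing chain: intensity normalization, Frankfort-horizontal
## reorientation, projections, and removal of the regions that disturb the
## bimodal bone/soft-tissue histogram (midface, anterior face, cervical
## vertebrae, temporal bone above the condylar heads).

#' Normalize intensities to span [0, 1]
#'
#' Affine map `(x - min) / (max - min)` so the minimum voxel maps to 0 and
#' the maximum to 1. Idempotent; errors on a constant volume.
#'
#' @param vol a [Volume3D-class]
#' @return a [Volume3D-class] with values spanning exactly [0, 1]
#' @export
normalizeIntensity <- function(vol) {
  stopifnot(is(vol, "Volume3D"))
  r <- range(vol@data)
  if (r[1] == r[2]) stop("degenerate image: constant intensity")
  vol@data <- (vol@data - r[1]) / (r[2] - r[1])
  vol
}

#' Rotate the volume so the Frankfort plane is horizontal
#'
#' Rotates the volume in the sagittal (Y-Z) plane about the midpoint of the
#' orbit and meatus points so that the line through them has zero Z slope
#' (the head's Frankfort plane becomes parallel to the floor). Resampling is
#' bilinear in the rotation plane with zero fill outside the grid.
#'
#' @param vol a [Volume3D-class]
#' @param orbit,meatus numeric(3) world mm, the inferior orbital margin and
#'   superior external-auditory-meatus margin.
#' @return a [Volume3D-class]
#' @export
reorientToFrankfort <- function(vol, orbit, meatus) {
  stopifnot(is(vol, "Volume3D"))
  d <- meatus[2:3] - orbit[2:3]
  if (sqrt(sum((meatus - orbit)^2)) == 0) stop("orbit and meatus coincide")
  phi <- atan2(d[2], d[1])  # slope angle of the line in (Y, Z)
  ## a line has no direction: reduce to (-pi/2, pi/2]
  if (phi > pi / 2) phi <- phi - pi
  if (phi <= -pi / 2) phi <- phi + pi
  if (phi == 0) return(vol)
  ctr <- (orbit[2:3] + meatus[2:3]) / 2
  yy <- .axisCoords(vol, 2)
  zz <- .axisCoords(vol, 3)
  gy <- matrix(yy, length(yy), length(zz))
  gz <- matrix(zz, length(yy), length(zz), byrow = TRUE)
  ## output voxel at (y,z) takes its value from rot(+phi) about ctr
  cph <- cos(phi); sph <- sin(phi)
  sy <- ctr[1] + cph * (gy - ctr[1]) - sph * (gz - ctr[2])
  sz <- ctr[2] + sph * (gy - ctr[1]) + cph * (gz - ctr[2])
  si <- (sy - vol@origin[2]) / vol@spacing[2] + 1
  sj <- (sz - vol@origin[3]) / vol@spacing[3] + 1
  out <- array(0, dim(vol@data))
  for (i in seq_len(dim(vol@data)[1])) {
    out[i, , ] <- .bilinear(vol@data[i, , ], as.numeric(si), as.numeric(sj))
  }
  vol@data <- out
  vol
}

#' Project a volume to 2D
#'
#' Maximum- or mean-intensity projection along one world axis. The returned
#' image keeps the spacing and origin of the two remaining axes, in X, Y, Z
#' order.
#'
#' @param vol a [Volume3D-class]
#' @param axis one of "X", "Y", "Z"
#' @param mode "max" (MIP) or "mean" (average intensity projection)
#' @return an [Image2D-class]
#' @export
projectVolume <- function(vol, axis = c("Z", "X", "Y"), mode = c("max", "mean")) {
  stopifnot(is(vol, "Volume3D"))
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  ax <- match(axis, c("X", "Y", "Z"))
  keep <- setdiff(1:3, ax)
  fun <- if (mode == "max") max else mean
  m <- apply(vol@data, keep, fun)
  image2D(m, spacing = vol@spacing[keep], origin = vol@origin[keep],
          axes = c("X", "Y", "Z")[keep])
}

#' Remove the half-space superior to a line in a projection view
#'
#' Given two points in the coronal (`viewAxis = "Y"`, plane X-Z) or sagittal
#' (`viewAxis = "X"`, plane Y-Z) projection plane, zeroes every voxel whose
#' projected coordinate lies strictly on the superior (+Z) side of the
#' infinite line through them, through the full extent of the view axis.
#'
#' @param vol a [Volume3D-class]
#' @param viewAxis "X" (sagittal view) or "Y" (coronal view)
#' @param p1,p2 numeric(2) points in the projection plane, mm: (Y, Z) for
#'   viewAxis "X", (X, Z) for viewAxis "Y".
#' @return a [Volume3D-class]
#' @export
removeSuperiorHalfplane <- function(vol, viewAxis = c("X", "Y"), p1, p2) {
  stopifnot(is(vol, "Volume3D"))
  viewAxis <- match.arg(viewAxis)
  if (isTRUE(all.equal(p1, p2))) stop("p1 and p2 must be distinct")
  if (p1[1] == p2[1])
    stop("vertical line: superior side is undefined")
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  inPlane <- if (viewAxis == "X") 2L else 1L
  u <- .axisCoords(vol, inPlane)
  z <- .axisCoords(vol, 3)
  lineZ <- p1[2] + slope * (u - p1[1])
  above <- outer(lineZ, z, function(l, zz) zz > l)  # u x z
  if (viewAxis == "X") {
    for (i in seq_len(dim(vol@data)[1])) vol@data[i, , ][above] <- 0
  } else {
    for (j in seq_len(dim(vol@data)[2])) vol@data[, j, ][above] <- 0
  }
  vol
}

#' Detect and remove the cervical vertebrae
#'
#' Takes the axial maximum-intensity projection of the occlusal band
#' `[occlusalZ - toothLength, occlusalZ]`, Otsu-binarizes it, and labels its
#' 8-connected components. The largest component is taken as the mandibular
#' arch; every other component whose centroid lies posterior (smaller Y) to
#' the arch centroid is labeled vertebra. The union of vertebral components
#' is scaled by `vertebraMagnification` about its own centroid and the
#' resulting axial footprint is zeroed through the full Z extent.
#'
#' @param vol a [Volume3D-class], intensities in [0, 1]
#' @param occlusalZ world Z of the occlusal plane, mm
#' @param config a [PipelineConfig-class]
#' @return a [Volume3D-class]
#' @export
removeCervicalVertebrae <- function(vol, occlusalZ, config = pipelineConfig()) {
  stopifnot(is(vol, "Volume3D"))
  kLo <- .zToSlice(vol, occlusalZ - config@toothLength)
  kHi <- .zToSlice(vol, occlusalZ)
  zr <- range(.axisCoords(vol, 3))
  if (occlusalZ < zr[1] || occlusalZ - config@toothLength > zr[2])
    stop("occlusal band does not intersect the volume")
  mip <- apply(vol@data[, , kLo:kHi, drop = FALSE], c(1, 2), max)
  b <- .binarizeMat(mip)
  if (!any(b)) {
    warning("no foreground in the occlusal band; volume unchanged")
    return(vol)
  }
  lab <- .labelComponents(b)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) < 2L) return(vol)
  archLab <- which.max(sizes)
  nr <- nrow(b)
  fg <- which(lab > 0L)
  jj <- ((fg - 1L) %/% nr) + 1L
  centY <- tapply(jj, lab[fg], mean)  # per-label centroid, column index
  vert <- setdiff(which(centY < centY[[as.character(archLab)]]), archLab)
  if (!length(vert)) return(vol)
  vmask <- matrix(lab %in% vert, nrow(b), ncol(b))
  vmask <- .magnifyRegion(vmask, config@vertebraMagnification)
  for (kk in seq_len(dim(vol@data)[3])) vol@data[, , kk][vmask] <- 0
  vol
}

#' Remove the temporal bone above the condylar heads
#'
#' For each condyle point, zeroes an ellipse in the sagittal (Y-Z) plane --
#' anteroposterior axis `condyleEllipse[1]`, superoinferior axis
#' `condyleEllipse[2]` mm, centered on the point -- through the full X
#' extent. Also returns the most inferior Z of the removed region, the
#' superior stopping plane for the cumulative binarization.
#'
#' @param vol a [Volume3D-class]
#' @param condyleA,condyleB numeric(3) world mm, points near the two condyle
#'   tops (picked on the sagittal average-intensity projection).
#' @param config a [PipelineConfig-class]
#' @return list with elements `volume` ([Volume3D-class]) and `stopZ` (mm)
#' @export
removeCondyleCaps <- function(vol, condyleA, condyleB,
                              config = pipelineConfig()) {
  stopifnot(is(vol, "Volume3D"))
  lo <- vol@origin - vol@spacing / 2
  hi <- vol@origin + (dim(vol@data) - 0.5) * vol@spacing
  for (p in list(condyleA, condyleB)) {
    if (any(p < lo) || any(p > hi)) stop("condyle point outside the volume")
  }
  ay <- config@condyleEllipse[1] / 2
  az <- config@condyleEllipse[2] / 2
  yy <- .axisCoords(vol, 2)
  zz <- .axisCoords(vol, 3)
  gy <- matrix(yy, length(yy), length(zz))
  gz <- matrix(zz, length(yy), length(zz), byrow = TRUE)
  inEll <- matrix(FALSE, length(yy), length(zz))
  for (p in list(condyleA, condyleB)) {
    inEll <- inEll | (((gy - p[2]) / ay)^2 + ((gz - p[3]) / az)^2 <= 1)
  }
  for (i in seq_len(dim(vol@data)[1])) vol@data[i, , ][inEll] <- 0
  stopZ <- min(condyleA[3], condyleB[3]) - az
  list(volume = vol, stopZ = stopZ)
}
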