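#' Construct a 3D volume
#'
#' @param data numeric 3D array (X, Y, Z axis order of the package convention).
#' @param spacing numeric(3) mm per voxel.
#' @param origin numeric(3) world mm of voxel (0,0,0). Default centers the
#'   grid on the world origin.
#' @return a [Volume3D-class]
#' @export
volume3D <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (is.null(origin)) origin <- -(dim(data) - 1) * spacing / 2
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a binary 3D volume
#' @param data logical 3D array.
#' @inheritParams volume3D
#' @return a [BinaryVolume3D-class]
#' @export
binaryVolume3D <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (is.null(origin)) origin <- -(dim(data) - 1) * spacing / 2
  new("BinaryVolume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a 2D image
#' @param data numeric matrix.
#' @param spacing numeric(2) mm.
#' @param origin numeric(2) mm of pixel (0,0).
#' @param axes character(2), world axes of rows and columns.
#' @return an [Image2D-class]
#' @export
image2D <- function(data, spacing = c(1, 1), origin = c(0, 0),
                    axes = c("X", "Y")) {
  new("Image2D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axes = axes)
}

#' Construct a binary 2D image
#' @param data logical matrix.
#' @inheritParams image2D
#' @return a [BinaryImage2D-class]
#' @export
binaryImage2D <- function(data, spacing = c(1, 1), origin = c(0, 0),
                          axes = c("X", "Y")) {
  new("BinaryImage2D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axes = axes)
}

#' Construct a landmark set
#'
#' @param points a named list of numeric(3) world-mm coordinates, or a 10 x 3
#'   matrix with the landmark names as rownames.
#' @return a [LandmarkSet-class]
#' @export
landmarkSet <- function(points) {
  if (is.list(points)) {
    missing <- setdiff(.LANDMARK_NAMES, names(points))
    if (length(missing))
      stop("missing landmark key(s): ", paste(missing, collapse = ", "))
    points <- do.call(rbind, lapply(.LANDMARK_NAMES, function(nm) {
      p <- as.numeric(points[[nm]])
      if (length(p) != 3L) stop("landmark '", nm, "' must have 3 coordinates")
      p
    }))
    rownames(points) <- .LANDMARK_NAMES
  }
  colnames(points) <- c("X", "Y", "Z")
  new("LandmarkSet", points = points[.LANDMARK_NAMES, , drop = FALSE])
}

#' Names of the ten landmarks
#' @return character(10)
#' @export
landmarkNames <- function() .LANDMARK_NAMES

#' Look up one landmark
#' @param landmarks a [LandmarkSet-class]
#' @param name landmark name
#' @return numeric(3) world mm
#' @export
landmark <- function(landmarks, name) {
  stopifnot(is(landmarks, "LandmarkSet"))
  name <- match.arg(name, .LANDMARK_NAMES)
  landmarks@points[name, ]
}

#' Pipeline configuration with published defaults
#'
#' @param vertebraMagnification scaling applied to detected vertebral regions
#'   before removal (default 1.5).
#' @param maskMagnification scaling of the propagated binarization mask
#'   (default 1.2).
#' @param condyleEllipse full Y and Z axes of the condylar removal ellipse in
#'   mm (default c(15, 21)).
#' @param toothLength average tooth length in mm (default 20), the depth of
#'   the occlusal band.
#' @param kPrevSlices number of previous binary slices summed into the
#'   propagated mask (default 3).
#' @param thresholdGridStep candidate-threshold grid step for the
#'   area-matched average-arch threshold (default 0.01).
#' @param splineSmooth smoothing-spline parameter p in (0, 1]. The
#'   equivalent smoothing bandwidth is `((1-p)/p)^(1/4)` in units of the
#'   arc sampling step; the default 0.02 smooths over ~2.6 mm at 1 mm
#'   sampling, enough to suppress pixel-level jitter of the extracted
#'   centerline while preserving the ~10 mm arch-to-ramus transition.
#' @param thicknessStep arc-length step of the thickness profile in mm
#'   (default 1).
#' @return a [PipelineConfig-class]
#' @export
pipelineConfig <- function(vertebraMagnification = 1.5,
                           maskMagnification = 1.2,
                           condyleEllipse = c(15, 21),
                           toothLength = 20,
                           kPrevSlices = 3L,
                           thresholdGridStep = 0.01,
                           splineSmooth = 0.02,
                           thicknessStep = 1) {
  new("PipelineConfig",
      vertebraMagnification = vertebraMagnification,
      maskMagnification = maskMagnification,
      condyleEllipse = as.numeric(condyleEllipse),
      toothLength = toothLength,
      kPrevSlices = as.integer(kPrevSlices),
      thresholdGridStep = thresholdGridStep,
      splineSmooth = splineSmooth,
      thicknessStep = thicknessStep)
}

#' Arch image foreground area
#' @param arch an [ArchImage-class]
#' @return area in mm^2
#' @export
archArea <- function(arch) sum(arch@mask) * prod(arch@spacing)

## ---- internal geometry helpers ----

## world coordinates of all grid positions along one axis of a volume
.axisCoords <- function(vol, axis) {
  n <- dim(vol@data)[axis]
  vol@origin[axis] + (seq_len(n) - 1) * vol@spacing[axis]
}

## world -> (fractional) 0-based index
.worldToIndex <- function(vol, xyz) (xyz - vol@origin) / vol@spacing

## nearest Z slice index (1-based) for a world Z in mm
.zToSlice <- function(vol, z) {
  k <- round((z - vol@origin[3]) / vol@spacing[3]) + 1
  as.integer(pmin(pmax(k, 1L), dim(vol@data)[3]))
}

## bilinear sampling of matrix `m` at fractional 1-based coordinates (i, j);
## outside the grid returns `fill`
.bilinear <- function(m, i, j, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  i0 <- floor(i); j0 <- floor(j)
  di <- i - i0; dj <- j - j0
  ok <- i0 >= 1 & i0 + 1 <= nr & j0 >= 1 & j0 + 1 <= nc
  out <- rep(fill, length(i))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; dik <- di[ok]; djk <- dj[ok]
    v00 <- m[cbind(i0k, j0k)]
    v10 <- m[cbind(i0k + 1, j0k)]
    v01 <- m[cbind(i0k, j0k + 1)]
    v11 <- m[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - dik) * (1 - djk) + v10 * dik * (1 - djk) +
      v01 * (1 - dik) * djk + v11 * dik * djk
  }
  out
}

## nearest-neighbour sampling of matrix at fractional 1-based coordinates
.nearest <- function(m, i, j, fill = 0) {
  i <- round(i); j <- round(j)
  ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
  out <- rep(fill, length(i))
  if (any(ok)) out[ok] <- m[cbind(i[ok], j[ok])]
  out
}

## cumulative arc length of an n x 2 polyline
.polylineArc <- function(p) {
  seg <- sqrt(rowSums(diff(p)^2))
  c(0, cumsum(seg))
}

## resample an n x 2 polyline at given arc-length positions
.polylineAt <- function(p, arc, at) {
  cbind(stats::approx(arc, p[, 1], xout = at, rule = 2, ties = "ordered")$y,
        stats::approx(arc, p[, 2], xout = at, rule = 2, ties = "ordered")$y)
}
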