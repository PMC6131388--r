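## Per-subject 2D arch images and the cohort average arch shape.

#' Build the subject's axial arch image
#'
#' Maximum projection of the segmented mandible over the union of the
#' dental-arch and posterior-mandible Z bands, cleaned to its largest
#' 8-connected component, with the canine midpoint as the reference
#' coordinate for cohort superimposition.
#'
#' @param mask a [BinaryVolume3D-class] segmentation.
#' @param dentalBand numeric(2) `(zLo, zHi)` mm, the dental-arch band.
#' @param ramusBand numeric(2) `(zLo, zHi)` mm, the posterior band
#'   containing ramus and condyle.
#' @param canines numeric 2 x 3 matrix (rows right/left canine, world mm)
#'   or a list of two points.
#' @return an [ArchImage-class]
#' @export
buildArchImage <- function(mask, dentalBand, ramusBand, canines) {
  stopifnot(is(mask, "BinaryVolume3D"))
  if (is.list(canines)) canines <- do.call(rbind, canines)
  zz <- .axisCoords(mask, 3)
  sel <- (zz >= dentalBand[1] & zz <= dentalBand[2]) |
    (zz >= ramusBand[1] & zz <= ramusBand[2])
  if (!any(sel)) stop("bands do not intersect the mask Z extent")
  proj <- apply(mask@data[, , sel, drop = FALSE], c(1, 2), any)
  if (!any(proj)) stop("empty projection: no foreground in the bands")
  proj <- largestComponent(proj)
  ref <- colMeans(canines[, 1:2, drop = FALSE])
  new("ArchImage", mask = proj, spacing = mask@spacing[1:2],
      origin = mask@origin[1:2], reference = as.numeric(ref),
      canines = canines[, 1:2, drop = FALSE])
}

#' Superimpose arch images on the canine midpoint
#'
#' Translates every arch (nearest-pixel, no interpolation, keeping masks
#' binary) so its canine-midpoint reference lands on a common origin at
#' world (0, 0), on a canvas covering all translated arches, and averages
#' the binary values into a per-pixel frequency map (exact multiples of
#' 1/n).
#'
#' @param arches list of [ArchImage-class] with identical pixel spacing.
#' @return an [AverageArch-class] with the frequency map filled in;
#'   `threshold`/`mask` are set by [areaMatchedThreshold()].
#' @export
superimposeArches <- function(arches) {
  stopifnot(length(arches) >= 1)
  sp <- arches[[1]]@spacing
  for (a in arches) {
    if (max(abs(a@spacing - sp)) > 1e-9)
      stop("mixed pixel spacing: resample the arch images to a common grid first")
  }
  n <- length(arches)
  ## exact integer-pixel shift per arch, bringing the reference near (0,0);
  ## masks and canine points are shifted by the same amount so they stay
  ## mutually consistent to machine precision
  tshift <- lapply(arches, function(a) round(a@reference / sp))
  oShift <- lapply(seq_len(n), function(i)
    arches[[i]]@origin - tshift[[i]] * sp)
  ## common canvas lattice anchored on the first arch's grid phase
  base <- oShift[[1]]
  pix <- lapply(oShift, function(o) round((o - base) / sp))
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  for (i in seq_len(n)) {
    lo <- pmin(lo, pix[[i]])
    hi <- pmax(hi, pix[[i]] + dim(arches[[i]]@mask) - 1)
  }
  cdim <- as.integer(hi - lo + 1)
  freq <- matrix(0, cdim[1], cdim[2])
  canSum <- matrix(0, 2, 2)
  for (i in seq_len(n)) {
    a <- arches[[i]]
    i0 <- pix[[i]][1] - lo[1] + 1; j0 <- pix[[i]][2] - lo[2] + 1
    ii <- i0:(i0 + nrow(a@mask) - 1)
    jj <- j0:(j0 + ncol(a@mask) - 1)
    freq[ii, jj] <- freq[ii, jj] + a@mask
    canSum <- canSum + sweep(a@canines, 2, tshift[[i]] * sp)
  }
  freq <- freq / n
  new("AverageArch", freq = freq, spacing = sp,
      origin = as.numeric(base + lo * sp), nSubjects = as.integer(n),
      threshold = NA_real_, mask = freq >= 0.5,
      meanIndividualArea = mean(vapply(arches, archArea, numeric(1))),
      maskArea = NA_real_, canines = canSum / n)
}

#' Area-matched threshold for the average arch
#'
#' Scans the candidate thresholds `step, 2*step, ..., 1` and picks the one
#' whose thresholded frequency-map area is closest to the mean individual
#' arch area. Ties are broken toward the candidate nearest 0.5 (the value
#' the threshold approaches as the cohort grows), then toward the lower
#' candidate.
#'
#' @param avg an [AverageArch-class] (frequency map filled in).
#' @param individualAreas numeric vector of per-subject arch areas, mm^2;
#'   defaults to areas recorded during superimposition.
#' @param config a [PipelineConfig-class] (grid step).
#' @return the input [AverageArch-class] with `threshold`, `mask` and
#'   `maskArea` set.
#' @export
areaMatchedThreshold <- function(avg, individualAreas = NULL,
                                 config = pipelineConfig()) {
  stopifnot(is(avg, "AverageArch"))
  if (!length(avg@freq) || !any(avg@freq > 0))
    stop("empty frequency map")
  target <- if (is.null(individualAreas)) avg@meanIndividualArea
            else mean(individualAreas)
  step <- config@thresholdGridStep
  cand <- seq(step, 1, by = step)
  pxArea <- prod(avg@spacing)
  fr <- as.numeric(avg@freq)
  areas <- vapply(cand, function(t) sum(fr >= t) * pxArea, numeric(1))
  err <- abs(areas - target)
  best <- err <= min(err) + 1e-12
  ties <- which(best)
  t <- ties[order(abs(cand[ties] - 0.5), cand[ties])][1]
  avg@threshold <- cand[t]
  avg@mask <- avg@freq >= cand[t]
  avg@maskArea <- areas[t]
  avg@meanIndividualArea <- target
  avg
}

#' Centerline of a binary arch band
#'
#' Reduces the mask to its morphological skeleton (Zhang-Suen thinning),
#' iteratively prunes spur branches shorter than 5% of the total skeleton
#' length, takes the dominant path (the skeleton's weighted diameter), and
#' returns it as an ordered polyline in world mm running from the
#' right-posterior end to the left-posterior end.
#'
#' @param mask a [BinaryImage2D-class], [AverageArch-class] (its thresholded
#'   mask), or logical matrix with `spacing`/`origin` attributes assumed
#'   unit/zero.
#' @param spacing,origin geometry overrides when `mask` is a plain matrix.
#' @param maxBranchDepth error if any residual skeleton branch strays
#'   farther than this fraction of the path length from the dominant path
#'   (default 0.05; staircase artifacts of thinning stay within ~1 px).
#' @return n x 2 matrix of (X, Y) mm
#' @export
archCenterline <- function(mask, spacing = c(1, 1), origin = c(0, 0),
                           maxBranchDepth = 0.05) {
  if (is(mask, "AverageArch")) {
    spacing <- mask@spacing; origin <- mask@origin; m <- mask@mask
  } else if (is(mask, "BinaryImage2D")) {
    spacing <- mask@spacing; origin <- mask@origin; m <- mask@data
  } else m <- mask
  if (!any(m)) stop("empty mask")
  lab <- .labelComponents(m)
  if (max(lab) > 1L)
    stop("disconnected mask: ", max(lab), " components")
  sk <- .skeletonize(m)
  path <- .skeletonPath(sk)
  if (path$offDepth > max(2, maxBranchDepth * path$pathLength))
    stop("no single dominant skeleton path: ", path$nBranches,
         " side branch(es), deepest straying ", round(path$offDepth, 1),
         " px from the path")
  ## pixel -> world mm
  pts <- cbind(origin[1] + (path$path[, 1] - 1) * spacing[1],
               origin[2] + (path$path[, 2] - 1) * spacing[2])
  ## orient right (smaller X) end first
  if (pts[1, 1] > pts[nrow(pts), 1]) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}
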