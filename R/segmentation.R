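## Otsu thresholding and the cumulative (mask-propagated) binarization of
## the mandible.  Intensities are assumed normalized to [0, 1]
## (see normalizeIntensity); the histogram always uses `bins` equal-width
## bins on [0, 1] so thresholds are comparable across slices.

#' Otsu threshold of a set of intensities
#'
#' Returns the histogram bin edge maximizing the between-class variance
#' (equivalently, minimizing intra-class variance) of the two classes
#' `value <= t` and `value > t`, with ties broken toward the lower
#' threshold. Intensities are binned into `bins` equal-width bins on [0, 1].
#'
#' @param values numeric intensities in [0, 1].
#' @param bins number of histogram bins (default 256).
#' @return the threshold, a bin edge in (0, 1).
#' @export
otsuThreshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  v <- pmin(pmax(values, 0), 1)
  bin <- pmin(floor(v * bins) + 1L, as.integer(bins))
  counts <- tabulate(bin, nbins = bins)
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: all values fall in a single bin")
  mid <- (seq_len(bins) - 0.5) / bins
  n <- sum(counts)
  w0 <- cumsum(counts)[-bins] / n
  m0 <- cumsum(counts * mid)[-bins] / n
  mT <- sum(counts * mid) / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma <- rep(-Inf, bins - 1L)
  sigma[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  (which.max(sigma)) / bins
}

## matrix-level masked Otsu binarization; returns logical matrix
.binarizeMat <- function(m, mask = NULL, bins = 256L) {
  if (is.null(mask)) {
    vals <- m
  } else {
    if (!any(mask)) {
      warning("empty mask: returning all-background slice")
      return(matrix(FALSE, nrow(m), ncol(m)))
    }
    vals <- m[mask]
  }
  t <- tryCatch(otsuThreshold(vals, bins), error = function(e) NULL)
  if (is.null(t)) return(matrix(FALSE, nrow(m), ncol(m)))
  out <- m > t
  if (!is.null(mask)) out <- out & mask
  out
}

#' Otsu-binarize one 2D slice, optionally within a mask
#'
#' The threshold is computed from the masked pixels only; pixels outside the
#' mask are background. An empty mask yields an all-background result with a
#' warning; a degenerate (single-bin) histogram yields all-background.
#'
#' @param slice an [Image2D-class] or numeric matrix with values in [0, 1].
#' @param mask optional [BinaryImage2D-class] or logical matrix of the same
#'   shape.
#' @param bins histogram bins (default 256).
#' @return a [BinaryImage2D-class] (or logical matrix if `slice` was one).
#' @export
binarizeSlice <- function(slice, mask = NULL, bins = 256L) {
  m <- if (is(slice, "Image2D")) slice@data else slice
  mk <- if (is.null(mask)) NULL else if (is(mask, "Image2D")) mask@data else mask
  if (!is.null(mk) && !identical(dim(mk), dim(m)))
    stop("mask shape must match the slice")
  out <- .binarizeMat(m, mk, bins)
  if (is(slice, "Image2D"))
    binaryImage2D(out, spacing = slice@spacing, origin = slice@origin,
                  axes = slice@axes)
  else out
}

#' Cumulative (mask-propagated) binarization of a volume
#'
#' Binarizes axial slices from `zStart` upward to `zStop`. The first
#' `kPrevSlices` slices are binarized by unmasked Otsu; every later slice is
#' binarized within a mask formed by summing the previous `kPrevSlices`
#' binary slices, taking the nonzero support, and scaling it by
#' `maskMagnification` about its centroid. Confining the histogram to the
#' neighbourhood of anatomy already found makes the slice-wise threshold
#' robust to the slowly varying intensity bias typical of cone-beam CT. If
#' all previous slices are empty the slice falls back to unmasked Otsu.
#'
#' @param vol a [Volume3D-class] normalized to [0, 1].
#' @param zStart,zStop world Z in mm, `zStart < zStop` (inferior to
#'   superior). Slices outside the range are background.
#' @param config a [PipelineConfig-class].
#' @return a [BinaryVolume3D-class]
#' @export
cumulativeBinarize <- function(vol, zStart, zStop, config = pipelineConfig()) {
  stopifnot(is(vol, "Volume3D"))
  if (!(zStart < zStop)) stop("empty z-range: zStart must be < zStop")
  k0 <- .zToSlice(vol, zStart)
  k1 <- .zToSlice(vol, zStop)
  if (k1 < k0) stop("empty z-range after snapping to the grid")
  k <- config@kPrevSlices
  out <- array(FALSE, dim(vol@data))
  prev <- vector("list", 0)
  for (kk in k0:k1) {
    sl <- vol@data[, , kk]
    if (length(prev) < k) {
      b <- .binarizeMat(sl)
    } else {
      msum <- Reduce(`+`, lapply(prev, function(x) x * 1L))
      support <- msum > 0L
      if (!any(support)) {
        b <- .binarizeMat(sl)
      } else {
        ## the magnified copy alone need not contain a non-convex support
        ## (scaling moves a U-band outward), so keep the union
        mask <- support | .magnifyRegion(support, config@maskMagnification)
        b <- suppressWarnings(.binarizeMat(sl, mask))
      }
    }
    out[, , kk] <- b
    prev <- c(prev, list(b))
    if (length(prev) > k) prev <- prev[-1]
  }
  binaryVolume3D(out, spacing = vol@spacing, origin = vol@origin)
}
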