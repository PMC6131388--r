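## Focal trough geometry: mirror-symmetrization about the midsagittal axis,
## smoothing-spline fits of the center and of the buccal/lingual boundaries
## (matched along center normals), the thickness profile, regional minima,
## and the dental-arch-to-ramus transition.

#' Mirror-symmetrize a polyline about a vertical axis
#'
#' Splits the polyline where it crosses the midsagittal line `X = axisX`,
#' pairs the two halves at matching arc-length fractions measured from the
#' crossing, averages each pair's lateral offset and Y, and mirrors the
#' averaged half back to both sides. The panoramic focal trough is built
#' symmetric, so right and left measurements are pooled this way before
#' fitting.
#'
#' @param points n x 2 polyline (mm), ordered from one end to the other.
#' @param axisX midsagittal X (mm).
#' @param nSamples arc-length resampling resolution per half (default:
#'   the input size, at least 100).
#' @return a symmetric m x 2 polyline ordered right end to left end.
#' @export
symmetrizePolyline <- function(points, axisX, nSamples = NULL) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 3)
  dx <- points[, 1] - axisX
  cross <- which(dx[-1] * dx[-nrow(points)] <= 0)
  if (!length(cross) || all(dx > 0) || all(dx < 0))
    stop("one-sided input: polyline does not cross the axis")
  i <- cross[1]
  ## interpolated apex at the crossing
  f <- if (dx[i + 1] == dx[i]) 0 else dx[i] / (dx[i] - dx[i + 1])
  apex <- points[i, ] + f * (points[i + 1, ] - points[i, ])
  firstHalf <- rbind(points[seq_len(i), , drop = FALSE], apex)[seq(i + 1, 1), , drop = FALSE]
  secondHalf <- rbind(apex, points[seq(i + 1, nrow(points)), , drop = FALSE])
  ## orient: "right" = the half on the smaller-X side
  if (mean(firstHalf[, 1]) <= axisX) {
    right <- firstHalf; left <- secondHalf
  } else {
    right <- secondHalf; left <- firstHalf
  }
  if (is.null(nSamples)) nSamples <- max(nrow(points), 100L)
  aR <- .polylineArc(right); aL <- .polylineArc(left)
  fr <- seq(0, 1, length.out = nSamples)
  pR <- .polylineAt(right, aR / max(aR), fr)
  pL <- .polylineAt(left, aL / max(aL), fr)
  dMean <- ((axisX - pR[, 1]) + (pL[, 1] - axisX)) / 2
  yMean <- (pR[, 2] + pL[, 2]) / 2
  out <- rbind(
    cbind(axisX - rev(dMean), rev(yMean))[seq_len(nSamples - 1), , drop = FALSE],
    cbind(axisX + dMean, yMean))
  out
}

## march from `p` along direction `n` (unit) until the bilinear mask value
## drops below 0.5; returns the exit distance or NA
.marchToBoundary <- function(m, spacing, origin, p, n, maxDist = 60,
                             step = NULL) {
  if (is.null(step)) step <- 0.25 * min(spacing)
  t <- seq(0, maxDist, by = step)
  px <- p[1] + t * n[1]; py <- p[2] + t * n[2]
  i <- (px - origin[1]) / spacing[1] + 1
  j <- (py - origin[2]) / spacing[2] + 1
  v <- .bilinear(m * 1, i, j, fill = 0)
  out <- which(v < 0.5)
  if (!length(out) || out[1] == 1L) return(NA_real_)
  k <- out[1]
  ## linear refinement between the last inside and first outside sample
  frac <- (v[k - 1] - 0.5) / (v[k - 1] - v[k])
  t[k - 1] + frac * step
}

#' Fit the focal trough to an average arch mask
#'
#' Fits the trough center as smoothing splines (X and Y against signed arc
#' length) through the symmetrized centerline, then finds the buccal
#' (outer) and lingual (inner) boundaries by intersecting the local center
#' normal with the mask contour at each arc sample, symmetrizing, and
#' fitting the same way. Samples closer to the path ends than half the
#' local trough thickness are dropped (the skeleton is biased by the cut
#' ends there).
#'
#' @param mask an [AverageArch-class] (thresholded mask) or
#'   [BinaryImage2D-class].
#' @param centerline n x 2 polyline from [archCenterline()], mm.
#' @param canines 2 x 2 matrix of the canine contact points (mm).
#' @param config a [PipelineConfig-class].
#' @param maxFailFraction error if more than this fraction of normals fails
#'   to hit both contours (default 0.05).
#' @return a [TroughModel-class]
#' @export
fitTrough <- function(mask, centerline, canines, config = pipelineConfig(),
                      maxFailFraction = 0.05) {
  if (is(mask, "AverageArch")) {
    m <- mask@mask; sp <- mask@spacing; orig <- mask@origin
  } else if (is(mask, "BinaryImage2D")) {
    m <- mask@data; sp <- mask@spacing; orig <- mask@origin
  } else stop("mask must be an AverageArch or BinaryImage2D")
  if (is.list(canines)) canines <- do.call(rbind, canines)
  canineMid <- colMeans(canines[, 1:2, drop = FALSE])
  axisX <- canineMid[1]
  p <- config@splineSmooth

  sym <- symmetrizePolyline(centerline, axisX)
  arc <- .polylineArc(sym)
  s <- arc - arc[(nrow(sym) + 1) / 2]   # signed, 0 at the apex
  cx0 <- fitSmoothingSpline(s, sym[, 1], p)
  cy0 <- fitSmoothingSpline(s, sym[, 2], p)

  ## symmetric sample grid
  h <- config@thicknessStep
  sMax <- min(-s[1], s[length(s)])
  sg <- seq(0, sMax, by = h)
  sg <- sort(unique(c(-sg, sg)))
  P <- cbind(evalSpline(cx0, sg), evalSpline(cy0, sg))
  Tn <- cbind(evalSpline(cx0, sg, 1L), evalSpline(cy0, sg, 1L))
  Tn <- Tn / sqrt(rowSums(Tn^2))
  Nn <- cbind(-Tn[, 2], Tn[, 1])
  ## orient normals outward (away from the mask centroid)
  fg <- which(m)
  cen <- c(orig[1] + (mean((fg - 1) %% nrow(m)) ) * sp[1],
           orig[2] + (mean((fg - 1) %/% nrow(m))) * sp[2])
  flip <- rowSums(Nn * sweep(P, 2, cen)) < 0
  Nn[flip, ] <- -Nn[flip, ]

  nS <- length(sg)
  march <- function(P, Nn) {
    dB <- dL <- rep(NA_real_, nS)
    for (i in seq_len(nS)) {
      dB[i] <- .marchToBoundary(m, sp, orig, P[i, ], Nn[i, ])
      dL[i] <- .marchToBoundary(m, sp, orig, P[i, ], -Nn[i, ])
    }
    list(dB = dB, dL = dL)
  }
  bd <- march(P, Nn)
  fail <- is.na(bd$dB) | is.na(bd$dL)
  if (mean(fail) > maxFailFraction)
    stop("normals failed to hit both contours at ",
         round(100 * mean(fail)), "% of samples")
  ## refine the center to the boundary mid-curve: the skeleton is accurate
  ## to about half a pixel only, while the bilinear edge crossings are
  ## sub-pixel; the mid-curve removes the skeleton's quantization bias
  shift <- (bd$dB - bd$dL) / 2
  shift[fail] <- 0
  Pr <- P + Nn * shift
  ## enforce exact mirror symmetry of the refined samples about the axis
  ## (x odd, y even in the signed arc parameter)
  Pr[, 1] <- axisX + ((Pr[, 1] - axisX) - rev(Pr[, 1] - axisX)) / 2
  Pr[, 2] <- (Pr[, 2] + rev(Pr[, 2])) / 2
  cx0 <- fitSmoothingSpline(sg, Pr[, 1], p)
  cy0 <- fitSmoothingSpline(sg, Pr[, 2], p)
  P <- cbind(evalSpline(cx0, sg), evalSpline(cy0, sg))
  Tn <- cbind(evalSpline(cx0, sg, 1L), evalSpline(cy0, sg, 1L))
  Tn <- Tn / sqrt(rowSums(Tn^2))
  Nn <- cbind(-Tn[, 2], Tn[, 1])
  flip <- rowSums(Nn * sweep(P, 2, cen)) < 0
  Nn[flip, ] <- -Nn[flip, ]
  bd <- march(P, Nn)
  dB <- bd$dB; dL <- bd$dL
  fail <- is.na(dB) | is.na(dL)
  if (mean(fail) > maxFailFraction)
    stop("normals failed to hit both contours at ",
         round(100 * mean(fail)), "% of samples")
  ## trim path-end samples (within half the local thickness of the ends)
  wHalf <- stats::median(dB + dL, na.rm = TRUE) / 2
  keep <- !fail & (sMax - abs(sg)) > wHalf
  if (sum(keep) < 8) stop("too few valid samples along the centerline")
  ## pool mirror-symmetric samples: average d(s) with d(-s)
  dBs <- (dB + dB[nS:1]) / 2
  dLs <- (dL + dL[nS:1]) / 2
  keep <- keep & keep[nS:1]
  sgk <- sg[keep]
  Pk <- cbind(evalSpline(cx0, sgk), evalSpline(cy0, sgk))
  Nk <- Nn[keep, , drop = FALSE]
  ## refit the center on the kept range; boundaries from symmetric offsets
  center <- fittedCurve(fitSmoothingSpline(sgk, Pk[, 1], p),
                        fitSmoothingSpline(sgk, Pk[, 2], p))
  bPts <- Pk + Nk * dBs[keep]
  lPts <- Pk - Nk * dLs[keep]
  buccal <- fittedCurve(fitSmoothingSpline(sgk, bPts[, 1], p),
                        fitSmoothingSpline(sgk, bPts[, 2], p))
  lingual <- fittedCurve(fitSmoothingSpline(sgk, lPts[, 1], p),
                         fitSmoothingSpline(sgk, lPts[, 2], p))
  ## canine arc positions on the center
  sFine <- seq(min(sgk), max(sgk), by = 0.1)
  Cf <- cbind(evalSpline(center@x, sFine), evalSpline(center@y, sFine))
  sR <- sFine[which.min((Cf[, 1] - canines[1, 1])^2 + (Cf[, 2] - canines[1, 2])^2)]
  sL <- sFine[which.min((Cf[, 1] - canines[2, 1])^2 + (Cf[, 2] - canines[2, 2])^2)]
  new("TroughModel", center = center, buccal = buccal, lingual = lingual,
      canineMid = as.numeric(canineMid), canineS = c(sR, sL))
}

#' Thickness profile of the focal trough
#'
#' Samples the trough center at the configured arc-length step and measures
#' the buccal-to-lingual distance along the center normal at each sample
#' (the boundaries are parameterized by the center arc length through their
#' construction, so corresponding parameters lie on the same normal). The
#' trough is symmetric, so the profile runs from the anterior midline
#' (s = 0) to the posterior end of one side.
#'
#' @param model a [TroughModel-class]
#' @param config a [PipelineConfig-class]
#' @return a [ThicknessProfile-class]
#' @export
thicknessProfile <- function(model, config = pipelineConfig()) {
  dom <- curveDomain(model@center)
  sEnd <- min(-dom[1], dom[2])
  s <- seq(0, sEnd, by = config@thicknessStep)
  B <- evalCurve(model@buccal, s)
  L <- evalCurve(model@lingual, s)
  th <- sqrt(rowSums((B - L)^2))
  canineS <- mean(abs(model@canineS))
  mins <- .regionalMins(s, th, canineS)
  new("ThicknessProfile", s = s, thickness = th, canineS = canineS,
      anteriorMin = mins[1], posteriorMin = mins[2])
}

.regionalMins <- function(s, th, canineS) {
  ant <- th[s <= canineS]
  post <- th[s > canineS]
  if (!length(ant)) stop("empty anterior region (canine at or before s = 0)")
  if (!length(post)) stop("empty posterior region (canine at or beyond the end)")
  c(min(ant), min(post))
}

#' Regional minimum thickness
#'
#' The minimum trough thickness anterior to the canine (midline to the
#' canine arc position, the incisor-to-canine region) and posterior to it
#' (canine to the posterior end, premolars to condylar head).
#'
#' @param profile a [ThicknessProfile-class]
#' @return named numeric(2): `anterior`, `posterior` (mm)
#' @export
regionalMinima <- function(profile) {
  stopifnot(is(profile, "ThicknessProfile"))
  mins <- .regionalMins(profile@s, profile@thickness, profile@canineS)
  c(anterior = mins[1], posterior = mins[2])
}

#' Locate the dental-arch-to-ramus transition
#'
#' Expresses the trough center of one side as lateral offset x(u) against
#' the posterior coordinate u (mm posterior to the canine midpoint). Along
#' the dental arch the second derivative of x(u) is nonzero; on the
#' straight ramus it vanishes. The transition is the onset of the
#' vanishing-second-derivative segment, located by segmented least
#' squares: the center is fit by a line plus a one-sided quadratic hinge
#' `c2 * (uT - u)^2` for `u < uT` (the leading term of any smooth curve
#' departing from a straight segment), and the changepoint `uT` minimizing
#' the residual sum of squares is the transition. The slope is the tangent
#' angle of the straight segment to the midsagittal axis. Both sides are
#' symmetric by construction, so one side is measured.
#'
#' @param model a [TroughModel-class]
#' @param straightTol straightness tolerance as a fraction of the posterior
#'   extent (default 0.003): if a single line explains the whole curve to
#'   within this, there is no transition. Relative, so locations scale
#'   linearly under uniform scaling of the arch.
#' @param hingeWindow length of curved arch included anterior to each
#'   candidate changepoint when fitting the hinge, as a fraction of the
#'   posterior extent (default 0.25), keeping the quadratic leading-term
#'   approximation local and the detector scale-free.
#' @return a [TransitionResult-class]
#' @export
locateTransition <- function(model, straightTol = 0.003, hingeWindow = 0.25) {
  dom <- curveDomain(model@center)
  sg <- seq(0, dom[2], by = 0.1)
  X <- abs(evalSpline(model@center@x, sg) - model@canineMid[1])
  U <- model@canineMid[2] - evalSpline(model@center@y, sg)
  dUds <- -evalSpline(model@center@y, sg, 1L)
  ok <- U > 0.5 & dUds > 1e-6
  if (sum(ok) < 10)
    stop("center curve does not extend posterior to the canine midpoint")
  i0 <- which(ok)[1]
  sel <- seq(i0, length(sg))
  sel <- sel[seq_len(max(which(cumprod(ok[sel]) > 0)))]  # contiguous run
  X <- X[sel]; U <- U[sel]
  uEnd <- max(U)
  ## straightness check: a line already explains the whole curve
  lineAll <- stats::lm.fit(cbind(1, U), X)
  eps <- straightTol * uEnd
  if (max(abs(lineAll$residuals)) < eps)
    stop("no transition: center is straight over the posterior range")
  uMin <- min(U)
  W <- hingeWindow * (uEnd - uMin)
  cands <- seq(uMin + 1, uEnd - 2, by = 0.1)
  if (!length(cands)) stop("no transition: posterior range too short")
  ## line plus a hinge whose quadratic growth is clipped beyond W (with a
  ## slope-matched linear continuation), fit over the whole posterior
  ## range: the clipping keeps the quadratic expansion local while the
  ## full-range residual prevents the window-sliding degeneracy of a
  ## purely local fit
  bestRss <- Inf; bestU <- NA_real_; bestCoef <- NULL
  for (uT in cands) {
    h <- pmin(pmax(uT - U, 0), W)^2 + 2 * W * pmax(uT - W - U, 0)
    f <- stats::lm.fit(cbind(1, U, h), X)
    rss <- sum(f$residuals^2)
    if (rss < bestRss) { bestRss <- rss; bestU <- uT; bestCoef <- f$coefficients }
  }
  c0 <- unname(bestCoef[1]); c1 <- unname(bestCoef[2])
  new("TransitionResult",
      lateral = abs(c0 + c1 * bestU),
      posterior = as.numeric(bestU),
      slope = atan(abs(c1)) * 180 / pi)
}
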