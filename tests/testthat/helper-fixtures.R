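## Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## default phantom (the study conditions) + its subject-level pipeline run
defaultPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- generatePhantom(phantomSpec())
  .fixtures$phantom
}

defaultSubjectRun <- function() {
  if (is.null(.fixtures$subject)) {
    ph <- defaultPhantom()
    .fixtures$subject <- runSubject(ph$volume, ph$truth@landmarks,
                                    subjectId = "fixture")
  }
  .fixtures$subject
}

defaultCohortRun <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- runCohort(list(defaultSubjectRun()$arch))
  .fixtures$cohort
}

## clean phantom: no confounders, no noise, no bias
cleanPhantom <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- generatePhantom(phantomSpec(
      includeSoftTissue = FALSE, includeVertebra = FALSE,
      includeCranium = FALSE, noiseSd = 0, biasAmplitude = 0))
  .fixtures$clean
}

## half-annulus band mask (r1 = 40, r2 = 55 mm, 0.5 mm pixels), open side
## posterior; returns the BinaryImage2D, the canine points on the mid
## radius, and the annulus geometry
halfAnnulus <- function(r1 = 40, r2 = 55, px = 0.5) {
  nx <- round(2 * (r2 + 5) / px) + 1
  ny <- round((r2 + 4) / px) + 1
  orig <- c(-(nx - 1) / 2 * px, -2)
  gx <- orig[1] + (0:(nx - 1)) * px
  gy <- orig[2] + (0:(ny - 1)) * px
  r <- sqrt(outer(gx^2, gy^2, `+`))
  ang <- outer(gx, gy, function(x, y) atan2(y, x))
  m <- r >= r1 & r <= r2 & ang > 0
  rc <- (r1 + r2) / 2
  list(mask = new("BinaryImage2D", data = m, spacing = c(px, px),
                  origin = orig, axes = c("X", "Y")),
       canines = rbind(c(-rc / sqrt(2), rc / sqrt(2)),
                       c(rc / sqrt(2), rc / sqrt(2))),
       r1 = r1, r2 = r2, rc = rc)
}

## vertical cylinder volume + truth (optionally with a soft slab appearing
## mid-stack and a multiplicative bias field)
cylinderPhantom <- function(withBiasAndSlab = FALSE, n = 128L, sp = 1.2) {
  g <- -(n - 1) * sp / 2 + (0:(n - 1)) * sp
  kz <- which(g >= -50 & g <= 50)
  disk <- outer((g + if (withBiasAndSlab) 35 else 0)^2, g^2, `+`) <=
    (if (withBiasAndSlab) 15 else 18)^2
  arr <- array(0.05, c(n, n, n))
  truth <- array(FALSE, c(n, n, n))
  By <- matrix(1 + 0.6 * g / max(abs(g)), n, n, byrow = TRUE)
  for (k in kz) {
    s <- matrix(0.05, n, n)
    if (withBiasAndSlab && g[k] > -40) s[g > 10, ] <- 0.30
    s[disk] <- if (withBiasAndSlab) 0.70 else 0.80
    arr[, , k] <- if (withBiasAndSlab) s * By else s
    truth[, , k][disk] <- TRUE
  }
  list(volume = normalizeIntensity(volume3D(arr, rep(sp, 3))),
       truth = truth, zSel = g >= -50 & g <= 50, z = g)
}

## exhaustive Otsu oracle: minimize intra-class (within-class) variance
## over all candidate bin edges -- an independent route to the optimum
otsuOracle <- function(values, bins = 256L) {
  v <- pmin(pmax(values, 0), 1)
  bin <- pmin(floor(v * bins) + 1L, bins)
  counts <- tabulate(bin, nbins = bins)
  mid <- (seq_len(bins) - 0.5) / bins
  n <- sum(counts)
  best <- Inf; bt <- NA_real_
  for (i in seq_len(bins - 1L)) {
    n0 <- sum(counts[1:i]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:i] * mid[1:i]) / n0
    m1 <- sum(counts[(i + 1):bins] * mid[(i + 1):bins]) / n1
    v0 <- sum(counts[1:i] * (mid[1:i] - m0)^2) / n0
    v1 <- sum(counts[(i + 1):bins] * (mid[(i + 1):bins] - m1)^2) / n1
    wcv <- (n0 * v0 + n1 * v1) / n
    if (wcv < best - 1e-15) { best <- wcv; bt <- i / bins }
  }
  bt
}

## analytic parabola-plus-ramus center model for transition tests
analyticTroughModel <- function(a = 25, b = 30, thetaDeg = 40, canineX = 10,
                                ramusLength = 40, scale = 1) {
  th <- thetaDeg * pi / 180
  xt <- b^2 / (2 * a * tan(th))
  xs <- seq(0, xt, length.out = 120)
  y <- -a * xs^2 / b^2
  ts <- seq(0, ramusLength, length.out = 80)[-1]
  xs <- c(xs, xt + ts * sin(th))
  y <- c(y, -a * xt^2 / b^2 - ts * cos(th))
  xs <- xs * scale; y <- y * scale
  pts <- cbind(c(-rev(xs[-1]), xs), c(rev(y[-1]), y))
  arc <- cumsum(c(0, sqrt(rowSums(diff(pts)^2))))
  s <- arc - arc[length(xs)]
  cx <- fitSmoothingSpline(s, pts[, 1], p = 1)
  cy <- fitSmoothingSpline(s, pts[, 2], p = 1)
  curve <- fittedCurve(cx, cy)
  yC <- -a * canineX^2 / b^2 * scale
  list(model = new("TroughModel", center = curve, buccal = curve,
                   lingual = curve, canineMid = c(0, yC),
                   canineS = c(-1, 1) * canineX * scale),
       joint = c(xt * scale, yC - (-a * xt^2 / b^2) * scale))
}
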