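test_that("symmetrization averages matched arc fractions and is idempotent", {
  ## symmetric input: unchanged (to tolerance)
  th <- seq(pi, 0, length.out = 101)
  poly <- cbind(50 * cos(th), 50 * sin(th))
  sym <- symmetrizePolyline(poly, 0)
  r <- sqrt(rowSums(sym^2))
  expect_lt(max(abs(r - 50)), 0.05)
  ## asymmetric pair averages to +/- mean offset at mean y
  poly2 <- rbind(c(-4, 0), c(-4, 12), c(0, 14), c(2, 10), c(2, 0))
  sym2 <- symmetrizePolyline(poly2, 0)
  expect_equal(max(sym2[, 1]), -min(sym2[, 1]), tolerance = 1e-9)
  ## ends: fractions 1 pair (-4, 0) with (2, 0) -> offsets +/-3 at y = 0
  expect_equal(sym2[1, ], c(-3, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sym2[nrow(sym2), ], c(3, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## idempotence at the curve level (sampling positions may differ)
  again <- symmetrizePolyline(sym2, 0)
  maxDev <- max(vapply(seq_len(nrow(again)), function(i) {
    sqrt(min((sym2[, 1] - again[i, 1])^2 + (sym2[, 2] - again[i, 2])^2))
  }, numeric(1)))
  expect_lt(maxDev, 0.1)
  ## one-sided input is refused
  expect_error(symmetrizePolyline(cbind(1:5, 1:5), 0), "one-sided")
})

test_that("the trough of a half annulus has the analytic radii and thickness", {
  ann <- halfAnnulus()
  cl <- archCenterline(ann$mask@data, spacing = ann$mask@spacing,
                       origin = ann$mask@origin)
  tr <- fitTrough(ann$mask, cl, ann$canines)
  dom <- curveDomain(tr@center)
  sg <- seq(dom[1], dom[2], by = 1)
  rc <- sqrt(rowSums(evalCurve(tr@center, sg)^2))
  rb <- sqrt(rowSums(evalCurve(tr@buccal, sg)^2))
  rl <- sqrt(rowSums(evalCurve(tr@lingual, sg)^2))
  expect_lt(sqrt(mean((rc - ann$rc)^2)), 0.5)  # 1 px at 0.5 mm
  expect_lt(sqrt(mean((rb - ann$r2)^2)), 0.5)
  expect_lt(sqrt(mean((rl - ann$r1)^2)), 0.5)
  prof <- thicknessProfile(tr)
  expect_true(all(abs(prof@thickness - (ann$r2 - ann$r1)) < 0.5))
  ## profile length tracks the fitted center's arc extent
  expect_lt(abs(max(prof@s) - dom[2]), 1.1)
  ## mirror symmetry of the fitted curves
  P <- evalCurve(tr@center, sg)
  Pm <- evalCurve(tr@center, -sg)
  expect_lt(max(abs(P[, 1] + Pm[, 1])), 1e-6)
  expect_lt(max(abs(P[, 2] - Pm[, 2])), 1e-6)
})

test_that("a rectangle band yields three parallel lines", {
  m <- matrix(FALSE, 160, 41)
  m[11:150, 11:31] <- TRUE  # 140 x 21 px band, width 20 mm at 1 mm px
  bi <- binaryImage2D(m, spacing = c(1, 1), origin = c(0, 0))
  cl <- archCenterline(m)
  can <- rbind(c(75, 20), c(85, 20))
  tr <- fitTrough(bi, cl, can)
  dom <- curveDomain(tr@center)
  sg <- seq(dom[1] + 2, dom[2] - 2, by = 1)
  yc <- evalCurve(tr@center, sg)[, 2]
  yb <- evalCurve(tr@buccal, sg)[, 2]
  yl <- evalCurve(tr@lingual, sg)[, 2]
  expect_lt(diff(range(yc)), 0.6)
  expect_lt(diff(range(yb)), 0.6)
  expect_lt(diff(range(yl)), 0.6)
  expect_equal(mean(abs(yb - yc)), 10, tolerance = 0.08)
  expect_equal(mean(abs(yc - yl)), 10, tolerance = 0.08)
})

test_that("a linear wedge's thickness slope is recovered", {
  ## circular-arc band whose width grows linearly with arc length
  px <- 0.5; R <- 50; w0 <- 8; slope <- 0.08
  nx <- 281; ny <- 151
  orig <- c(-(nx - 1) / 2 * px, -5)
  gx <- orig[1] + (0:(nx - 1)) * px
  gy <- orig[2] + (0:(ny - 1)) * px
  r <- sqrt(outer(gx^2, gy^2, `+`))
  ang <- outer(gx, gy, function(x, y) atan2(y, x))
  s <- R * abs(ang - pi / 2)      # arc length from the apex
  m <- ang > 0 & abs(r - R) <= (w0 + slope * s) / 2
  bi <- binaryImage2D(m, spacing = c(px, px), origin = orig)
  cl <- archCenterline(m, spacing = c(px, px), origin = orig)
  can <- rbind(c(-R / sqrt(2), R / sqrt(2)), c(R / sqrt(2), R / sqrt(2)))
  tr <- fitTrough(bi, cl, can)
  prof <- thicknessProfile(tr)
  keep <- prof@s > 5 & prof@s < max(prof@s) - 5
  fit <- stats::lm(prof@thickness[keep] ~ prof@s[keep])
  expect_lt(abs(coef(fit)[2] - slope) / slope, 0.05)
})

test_that("regional minima split the profile at the canine", {
  s <- seq(0, 100, by = 1)
  th <- 20 - 9 * exp(-(s - 20)^2 / 18) - 3 * exp(-(s - 80)^2 / 18)
  prof <- new("ThicknessProfile", s = s, thickness = th, canineS = 40,
              anteriorMin = 0.1, posteriorMin = 0.1)
  mins <- regionalMinima(prof)
  expect_equal(unname(mins["anterior"]), 11, tolerance = 1e-6)
  expect_equal(unname(mins["posterior"]), 17, tolerance = 1e-6)
  ## constant profile: both minima equal the constant
  prof2 <- new("ThicknessProfile", s = s, thickness = rep(12, length(s)),
               canineS = 40, anteriorMin = 12, posteriorMin = 12)
  expect_equal(unname(regionalMinima(prof2)), c(12, 12))
  prof3 <- prof; prof3@canineS <- 1000
  expect_error(regionalMinima(prof3), "posterior")
})

test_that("the transition of an analytic parabola-ramus joint is recovered", {
  am <- analyticTroughModel()
  res <- locateTransition(am$model)
  expect_equal(res@slope, 40, tolerance = 1)
  expect_lt(abs(res@lateral - am$joint[1]), 2)
  expect_lt(abs(res@posterior - am$joint[2]), 2)
})

test_that("transition slope is scale-free and location scales linearly", {
  r1 <- locateTransition(analyticTroughModel(scale = 1)$model)
  r2 <- locateTransition(analyticTroughModel(scale = 2)$model)
  expect_lt(abs(r1@slope - r2@slope), 0.5)
  expect_equal(r2@posterior / r1@posterior, 2, tolerance = 0.05)
  expect_equal(r2@lateral / r1@lateral, 2, tolerance = 0.05)
})

test_that("a straight center has no transition", {
  s <- seq(-60, 60, length.out = 80)
  th <- 40 * pi / 180
  cx <- fitSmoothingSpline(s, abs(s) * sin(th), p = 1)
  cy <- fitSmoothingSpline(s, -abs(s) * cos(th), p = 1)
  curve <- fittedCurve(cx, cy)
  model <- new("TroughModel", center = curve, buccal = curve,
               lingual = curve, canineMid = c(0, 0), canineS = c(-5, 5))
  expect_error(locateTransition(model), "no transition")
})
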