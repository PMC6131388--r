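test_that("the same seed reproduces a bit-identical phantom", {
  s <- phantomSpec(dim = c(48L, 48L, 48L), spacing = rep(2.4, 3), seed = 5L)
  a <- generatePhantom(s); b <- generatePhantom(s)
  expect_identical(gridData(a$volume), gridData(b$volume))
})

test_that("global Otsu on a clean phantom recovers the mandible almost exactly", {
  ph <- cleanPhantom()
  vol <- normalizeIntensity(ph$volume)
  t <- otsuThreshold(as.numeric(gridData(vol)))
  seg <- gridData(vol) > t
  expect_gte(diceCoefficient(seg, gridData(ph$truth@mask)), 0.99)
})

test_that("the ground-truth centerline tangent on the ramus equals the spec angle", {
  ph <- cleanPhantom()
  tr <- ph$truth
  ## finite differences on the truth polyline, left ramus segment
  sel <- tr@arcLength > max(tr@arcLength) - 20
  d <- diff(tr@centerline[sel, , drop = FALSE])
  ang <- atan2(d[, 1], -d[, 2]) * 180 / pi  # tangent angle to midsagittal
  expect_lt(max(abs(ang - 40)), 0.5)
})

test_that("canines lie on the centerline and the truth is mirror-symmetric", {
  ph <- cleanPhantom()
  tr <- ph$truth
  for (nm in c("canine_right", "canine_left")) {
    p <- landmark(tr@landmarks, nm)[1:2]
    d <- sqrt(min((tr@centerline[, 1] - p[1])^2 + (tr@centerline[, 2] - p[2])^2))
    expect_lt(d, 0.6)  # within half a voxel
  }
  ## centerline mirror-symmetric about the midsagittal plane
  flipped <- tr@centerline[nrow(tr@centerline):1, ]
  flipped[, 1] <- -flipped[, 1]
  expect_equal(flipped, tr@centerline, tolerance = 1e-9)
  ## clean volume and truth mask are mirror-symmetric voxelwise
  v <- gridData(ph$volume)
  expect_identical(v[dim(v)[1]:1, , ], v)
  m <- gridData(tr@mask)
  expect_identical(m[dim(m)[1]:1, , ], m)
})

test_that("projected band area matches the analytic band integral", {
  ## knob-free band at 0.5 mm axial sampling; projected area should equal
  ## integral(w ds) plus the two round end caps
  s <- phantomSpec(dim = c(308L, 308L, 48L), spacing = c(0.5, 0.5, 1.2),
                   ramusTopZ = 25, condyleRadius = 0,
                   includeSoftTissue = FALSE, includeVertebra = FALSE,
                   includeCranium = FALSE, noiseSd = 0, biasAmplitude = 0)
  ph <- generatePhantom(s)
  proj <- apply(gridData(ph$truth@mask), c(1, 2), any)
  area <- sum(proj) * 0.25
  w <- 12
  arcTotal <- 2 * max(ph$truth@arcLength)
  analytic <- w * arcTotal + pi * (w / 2)^2
  expect_lt(abs(area - analytic) / analytic, 0.02)
})

test_that("band self-intersection is rejected", {
  expect_error(generatePhantom(phantomSpec(bandWidth = 40)),
               "self-intersection")
})

test_that("cohorts reproduce the base spec at zero variability", {
  base <- phantomSpec(dim = c(48L, 48L, 48L), spacing = rep(2.4, 3))
  coh <- generateCohort(base, n = 3, variability = 0, seed = 9)
  expect_identical(gridData(coh[[1]]$volume), gridData(coh[[2]]$volume))
  expect_identical(gridData(coh[[2]]$volume), gridData(coh[[3]]$volume))
  ## n = 1 equals a single phantom generated with the derived sub-seed
  one <- generateCohort(base, n = 1, variability = 0, seed = 9)
  sub <- base; sub@seed <- as.integer(9 * 1009 + 1)
  expect_identical(gridData(one[[1]]$volume),
                   gridData(generatePhantom(sub)$volume))
})

test_that("cohort mean arch area stays near the base-spec area", {
  base <- phantomSpec(dim = c(96L, 96L, 64L), spacing = c(1.6, 1.6, 1.6),
                      includeSoftTissue = FALSE, includeVertebra = FALSE,
                      includeCranium = FALSE, noiseSd = 0, biasAmplitude = 0)
  coh <- generateCohort(base, n = 20, variability = 0.05, seed = 31)
  areas <- vapply(coh, function(s) {
    sum(apply(gridData(s$truth@mask), c(1, 2), any)) * 1.6^2
  }, numeric(1))
  baseArea <- sum(apply(gridData(generatePhantom(base)$truth@mask),
                        c(1, 2), any)) * 1.6^2
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - baseArea), 3 * se + 1e-9)
})
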