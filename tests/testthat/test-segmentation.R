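test_that("otsuThreshold separates perfectly bimodal data", {
  v <- c(rep(0.2, 500), rep(0.8, 500))
  t <- otsuThreshold(v)
  expect_gt(t, 0.2 - 1e-9)
  expect_lte(t, 0.8)
  expect_true(all(v[v > t] == 0.8))
  expect_true(all(v[v <= t] == 0.2))
  expect_error(otsuThreshold(rep(0.5, 100)), "degenerate")
})

test_that("otsuThreshold equals the exhaustive within-class-variance minimizer", {
  set.seed(99)
  for (rep in 1:25) {
    v <- switch(1 + rep %% 3,
                runif(400),
                c(rnorm(300, 0.3, 0.05), rnorm(200, 0.7, 0.08)),
                rbeta(350, 2, 5))
    expect_equal(otsuThreshold(v), otsuOracle(v))
  }
})

test_that("masked slice binarization confines foreground to the mask", {
  set.seed(5)
  sl <- matrix(runif(40 * 40, 0, 0.3), 40, 40)
  sl[10:20, 10:20] <- runif(121, 0.7, 0.9)
  b <- binarizeSlice(sl)
  expect_true(all(which(b) %in% which(sl > 0.5)))
  mask <- matrix(FALSE, 40, 40); mask[5:25, 5:25] <- TRUE
  bm <- binarizeSlice(sl, mask)
  expect_true(all(bm[!mask] == FALSE))
  expect_warning(b0 <- binarizeSlice(sl, matrix(FALSE, 40, 40)), "empty mask")
  expect_false(any(b0))
  expect_false(any(binarizeSlice(matrix(0, 8, 8))))
  expect_error(binarizeSlice(sl, matrix(TRUE, 3, 3)), "shape")
})

test_that("cumulative binarization recovers a noiseless cylinder", {
  cyl <- cylinderPhantom()
  seg <- cumulativeBinarize(cyl$volume, -50, 50)
  expect_gte(diceCoefficient(gridData(seg)[, , cyl$zSel],
                             cyl$truth[, , cyl$zSel]), 0.99)
  expect_error(cumulativeBinarize(cyl$volume, 10, 10), "z-range")
})

test_that("mask propagation confines and stabilizes against bias", {
  biased <- cylinderPhantom(withBiasAndSlab = TRUE)
  seg <- cumulativeBinarize(biased$volume, -50, 50)
  plain <- array(FALSE, dim(gridData(biased$volume)))
  for (k in which(biased$zSel))
    plain[, , k] <- binarizeSlice(gridData(biased$volume)[, , k])
  dCum <- diceCoefficient(gridData(seg)[, , biased$zSel],
                          biased$truth[, , biased$zSel])
  dPlain <- diceCoefficient(plain[, , biased$zSel],
                            biased$truth[, , biased$zSel])
  expect_gte(dCum, dPlain)
  expect_gte(dCum, 0.99)
  ## foreground on masked slices is a subset of the propagated mask:
  ## every slice's foreground stays near the previous slices' support
  cfg <- pipelineConfig()
  ks <- which(biased$zSel)
  for (k in ks[seq(5, length(ks), by = 17)]) {
    support <- gridData(seg)[, , k - 1] | gridData(seg)[, , k - 2] |
      gridData(seg)[, , k - 3]
    if (!any(support)) next
    mask <- support | archtrough:::.magnifyRegion(support,
                                                  cfg@maskMagnification)
    expect_true(all(which(gridData(seg)[, , k]) %in% which(mask)))
  }
})

test_that("empty propagated masks fall back to unmasked Otsu", {
  ## foreground only in the upper half: the first slices produce empty
  ## binaries, later slices must still recover via the fallback
  n <- 40L
  arr <- array(0.05, c(n, n, n))
  arr[15:25, 15:25, 25:40] <- 0.9
  vol <- normalizeIntensity(volume3D(arr, rep(1, 3)))
  seg <- cumulativeBinarize(vol, origin(vol)[3], origin(vol)[3] + 39)
  ## constant lower slices binarize to background; the first occupied
  ## slice recovers through the unmasked fallback
  expect_equal(sum(gridData(seg)[, , 20]), 0L)
  expect_equal(sum(gridData(seg)[, , 30]), 121L)
})

test_that("largestComponent keeps the biggest 8-connected blob", {
  m <- matrix(FALSE, 30, 30)
  m[2:11, 2:11] <- TRUE        # 100 px
  m[20:21, 20:22] <- TRUE      # 6 px
  out <- largestComponent(m)
  expect_equal(sum(out), 100L)
  expect_true(all(which(out) %in% which(m)))
  ## diagonal connectivity joins blobs
  m2 <- matrix(FALSE, 10, 10)
  m2[1:3, 1:3] <- TRUE; m2[4, 4] <- TRUE; m2[5:6, 5:6] <- TRUE
  expect_equal(sum(largestComponent(m2)), sum(m2))
  ## identity on a single blob, empty stays empty
  expect_identical(largestComponent(m2), m2)
  expect_equal(sum(largestComponent(matrix(FALSE, 5, 5))), 0L)
  ## BinaryImage2D in, BinaryImage2D out
  bi <- binaryImage2D(m, spacing = c(1, 1))
  expect_s4_class(largestComponent(bi), "BinaryImage2D")
})
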