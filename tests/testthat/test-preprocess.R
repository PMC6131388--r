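test_that("intensity normalization forces the [0,1] span and is idempotent", {
  arr <- array(runif(4^3, -1000, 3000), c(4, 4, 4))
  arr[1, 1, 1] <- -1000; arr[2, 2, 2] <- 3000; arr[3, 3, 3] <- 1000
  vol <- normalizeIntensity(volume3D(arr))
  expect_equal(gridData(vol)[1, 1, 1], 0)
  expect_equal(gridData(vol)[2, 2, 2], 1)
  expect_equal(gridData(vol)[3, 3, 3], 0.5)
  twice <- normalizeIntensity(vol)
  expect_equal(gridData(twice), gridData(vol))
  expect_error(normalizeIntensity(volume3D(array(7, c(3, 3, 3)))),
               "degenerate")
})

test_that("Frankfort reorientation levels the landmark line", {
  set.seed(21)
  arr <- array(runif(40^3), c(40, 40, 40))
  vol <- volume3D(arr, spacing = c(1, 1, 1), origin = c(-20, -20, -20))
  ## equal-Z points: identity
  same <- reorientToFrankfort(vol, c(0, 10, 5), c(0, -10, 5))
  expect_identical(gridData(same), arr)
  ## 10-degree line: transformed points end up level within one voxel
  rise <- 10 * tan(10 * pi / 180)
  orbit <- c(0, 10, 2 + rise); meatus <- c(0, -10, 2 - rise)
  out <- reorientToFrankfort(vol, orbit, meatus)
  pts <- lapply(landmarkNames(), function(nm) c(0, 0, 0))
  names(pts) <- landmarkNames()
  pts$frankfort_orbit <- orbit; pts$frankfort_meatus <- meatus
  pts$canine_right <- c(-1, 0, 0); pts$canine_left <- c(1, 0, 0)
  rot <- archtrough:::.reorientLandmarks(landmarkSet(pts), orbit, meatus)
  zz <- rot@points[c("frankfort_orbit", "frankfort_meatus"), 3]
  expect_lt(abs(diff(zz)), 1)
  ## the pivot voxel keeps its value exactly (fixed point on a voxel center)
  piv <- (orbit + meatus) / 2
  idx <- (piv - origin(vol)) / spacing(vol) + 1
  expect_equal(idx, round(idx))  # pivot sits on the grid by construction
  expect_equal(gridData(out)[idx[1], idx[2], idx[3]],
               gridData(vol)[idx[1], idx[2], idx[3]], tolerance = 1e-9)
  expect_error(reorientToFrankfort(vol, c(0, 1, 2), c(0, 1, 2)), "coincide")
})

test_that("projections reduce the right axis with the right statistic", {
  arr <- array(2, c(5, 7, 9))
  vol <- volume3D(arr)
  expect_equal(unique(as.numeric(gridData(projectVolume(vol, "Z", "mean")))), 2)
  arr2 <- array(0, c(5, 7, 9)); arr2[2, 3, 4] <- 5
  vol2 <- volume3D(arr2)
  mip <- projectVolume(vol2, "Z", "max")
  expect_equal(dim(gridData(mip)), c(5L, 7L))
  expect_equal(which(gridData(mip) == 5, arr.ind = TRUE)[1, ],
               c(row = 2L, col = 3L))
  for (ax in c("X", "Y", "Z")) {
    keep <- setdiff(1:3, match(ax, c("X", "Y", "Z")))
    expect_equal(dim(gridData(projectVolume(vol2, ax, "max"))),
                 dim(arr2)[keep])
  }
})

test_that("superior-halfplane removal matches a brute-force voxel test", {
  set.seed(4)
  arr <- array(runif(20^3, 0.5, 1), c(20, 20, 20))
  vol <- volume3D(arr, spacing = c(1, 1, 1))
  ## horizontal line: exact slab count
  z0 <- 3.2
  out <- removeSuperiorHalfplane(vol, "X", c(-5, z0), c(5, z0))
  zz <- origin(vol)[3] + (0:19) * 1
  expect_equal(sum(gridData(out) == 0), 400 * sum(zz > z0))
  ## oblique line vs brute force, both view axes
  for (va in c("X", "Y")) {
    p1 <- c(-4, -2); p2 <- c(6, 7)
    out <- removeSuperiorHalfplane(vol, va, p1, p2)
    slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
    inAx <- if (va == "X") 2 else 1
    cnt <- 0L
    for (i in 1:20) for (j in 1:20) for (k in 1:20) {
      w <- origin(vol) + (c(i, j, k) - 1) * spacing(vol)
      if (w[3] > p1[2] + slope * (w[inAx] - p1[1])) cnt <- cnt + 1L
    }
    expect_equal(sum(gridData(out) == 0), cnt)
  }
  ## line above the volume: unchanged
  keep <- removeSuperiorHalfplane(vol, "X", c(-5, 100), c(5, 101))
  expect_identical(gridData(keep), arr)
  expect_error(removeSuperiorHalfplane(vol, "X", c(1, 0), c(1, 5)),
               "vertical")
  expect_error(removeSuperiorHalfplane(vol, "X", c(1, 0), c(1, 0)),
               "distinct")
})

test_that("removal operations never increase intensity", {
  ph <- defaultPhantom()
  vol <- normalizeIntensity(ph$volume)
  lm <- ph$truth@landmarks
  v1 <- removeSuperiorHalfplane(vol, "Y",
                                landmark(lm, "coronal_right")[c(1, 3)],
                                landmark(lm, "coronal_left")[c(1, 3)])
  expect_true(all(gridData(v1) <= gridData(vol)))
  v2 <- removeCervicalVertebrae(v1, landmark(lm, "occlusal_anterior")[3])
  expect_true(all(gridData(v2) <= gridData(v1)))
  ## halfplane removals commute (both are voxelwise masks)
  a <- removeSuperiorHalfplane(
    removeSuperiorHalfplane(vol, "Y", c(-55, 46), c(55, 46)),
    "X", c(42, 0), c(12, 54.6))
  b <- removeSuperiorHalfplane(
    removeSuperiorHalfplane(vol, "X", c(42, 0), c(12, 54.6)),
    "Y", c(-55, 46), c(55, 46))
  expect_identical(gridData(a), gridData(b))
})

test_that("vertebral confounders are removed; anterior blobs are kept", {
  ## mandible + posterior cylinder only
  ph <- generatePhantom(phantomSpec(includeSoftTissue = FALSE,
                                    includeCranium = FALSE,
                                    noiseSd = 0, biasAmplitude = 0))
  vol <- normalizeIntensity(ph$volume)
  occ <- landmark(ph$truth@landmarks, "occlusal_anterior")[3]
  out <- removeCervicalVertebrae(vol, occ)
  ## the posterior cylinder footprint is zeroed through all Z
  vy <- -45
  i0 <- round((0 - origin(vol)[1]) / spacing(vol)[1]) + 1
  j0 <- round((vy - origin(vol)[2]) / spacing(vol)[2]) + 1
  expect_true(all(gridData(out)[i0, j0, ] == 0))
  ## remaining foreground is the mandible
  expect_gte(diceCoefficient(gridData(out) > 0.5, gridData(ph$truth@mask)),
             0.99)
  ## phantom without confounder: unchanged
  ph2 <- cleanPhantom()
  vol2 <- normalizeIntensity(ph2$volume)
  out2 <- removeCervicalVertebrae(vol2, 0)
  expect_identical(gridData(out2), gridData(vol2))
})

test_that("condylar cap removal zeroes the ellipse and reports the stop plane", {
  arr <- array(1, c(40, 40, 40))
  vol <- volume3D(arr, spacing = c(1, 1, 1))
  p <- c(0, 0, 0)
  res <- removeCondyleCaps(vol, p, p)
  expect_equal(res$stopZ, -10.5)
  ## zeroed count equals brute-force ellipse membership through all X
  cnt <- 0L
  for (j in 1:40) for (k in 1:40) {
    w <- origin(vol)[2:3] + (c(j, k) - 1)
    if ((w[1] / 7.5)^2 + (w[2] / 10.5)^2 <= 1) cnt <- cnt + 1L
  }
  expect_equal(sum(gridData(res$volume) == 0), cnt * 40L)
  ## two coincident points behave as one; distinct second point adds voxels
  res2 <- removeCondyleCaps(vol, p, c(0, 15, 5))
  expect_gt(sum(gridData(res2$volume) == 0), sum(gridData(res$volume) == 0))
  expect_equal(res2$stopZ, -10.5)
  expect_error(removeCondyleCaps(vol, c(0, 0, 1000), p), "outside")
})
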