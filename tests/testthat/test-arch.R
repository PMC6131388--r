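test_that("arch images project the selected bands and keep the reference", {
  run <- defaultSubjectRun()
  ph <- defaultPhantom()
  truthArch <- apply(gridData(ph$truth@mask), c(1, 2), any)
  expect_gte(diceCoefficient(run$arch@mask, truthArch), 0.95)
  expect_lt(abs(archArea(run$arch) - sum(truthArch) * 1.44) /
              (sum(truthArch) * 1.44), 0.05)
  ## reference = canine midpoint
  cm <- colMeans(ph$truth@landmarks@points[c("canine_right", "canine_left"),
                                           1:2])
  expect_equal(run$arch@reference, unname(cm))
  ## bands covering all Z equal the full union projection
  mk <- run$mask
  full <- buildArchImage(mk, c(-100, 0), c(0, 100),
                         ph$truth@landmarks@points[c("canine_right",
                                                     "canine_left"), ])
  expect_identical(full@mask,
                   largestComponent(apply(gridData(mk), c(1, 2), any)))
  expect_error(buildArchImage(mk, c(500, 600), c(700, 800),
                              ph$truth@landmarks@points[c("canine_right",
                                                          "canine_left"), ]),
               "bands")
})

test_that("superimposition produces exact 1/n frequencies and is translation-invariant", {
  m <- matrix(FALSE, 30, 30); m[10:20, 5:25] <- TRUE
  a1 <- new("ArchImage", mask = m, spacing = c(1, 1), origin = c(-15, -15),
            reference = c(0, 0), canines = rbind(c(-3, 0), c(3, 0)))
  ## identical arches: frequency stays binary and equals one arch
  avg <- superimposeArches(list(a1, a1, a1))
  expect_true(all(avg@freq %in% c(0, 1)))
  expect_equal(sum(avg@freq), sum(m))
  ## frequencies are multiples of 1/n for distinct arches
  m2 <- m; m2[1:5, 1:5] <- TRUE
  a2 <- new("ArchImage", mask = m2, spacing = c(1, 1), origin = c(-15, -15),
            reference = c(0, 0), canines = rbind(c(-3, 0), c(3, 0)))
  avg2 <- superimposeArches(list(a1, a2))
  expect_true(all(abs(avg2@freq * 2 - round(avg2@freq * 2)) < 1e-12))
  ## translating an arch and its reference by whole pixels changes nothing
  a3 <- new("ArchImage", mask = m, spacing = c(1, 1),
            origin = c(-15, -15) + c(5, 7),
            reference = c(5, 7), canines = rbind(c(2, 7), c(8, 7)))
  avgT <- superimposeArches(list(a3))
  avgR <- superimposeArches(list(a1))
  expect_identical(avgT@freq, avgR@freq)
  expect_equal(avgT@canines, avgR@canines)
  ## disjoint after alignment: max frequency one half
  m4 <- matrix(FALSE, 30, 30); m4[1:5, 1:5] <- TRUE
  a4 <- new("ArchImage", mask = m4, spacing = c(1, 1), origin = c(-15, -15),
            reference = c(0, 0), canines = rbind(c(-3, 0), c(3, 0)))
  expect_equal(max(superimposeArches(list(a1, a4))@freq), 0.5)
  ## mixed spacing is refused
  a5 <- new("ArchImage", mask = m, spacing = c(2, 2), origin = c(-15, -15),
            reference = c(0, 0), canines = rbind(c(-3, 0), c(3, 0)))
  expect_error(superimposeArches(list(a1, a5)), "spacing")
})

test_that("area-matched threshold follows the grid search and its tie rules", {
  m <- matrix(FALSE, 30, 30); m[10:20, 5:25] <- TRUE
  a1 <- new("ArchImage", mask = m, spacing = c(1, 1), origin = c(-15, -15),
            reference = c(0, 0), canines = rbind(c(-3, 0), c(3, 0)))
  ## identical arches: every threshold ties; rule picks 0.5
  avg <- areaMatchedThreshold(superimposeArches(list(a1, a1)))
  expect_equal(avg@threshold, 0.5)
  expect_equal(avg@maskArea, sum(m))
  ## nested arches: candidates <= 0.5 give the big area, > 0.5 the small;
  ## the chosen threshold must match an exhaustive grid search
  big <- matrix(FALSE, 40, 40); big[5:35, 5:35] <- TRUE
  small <- matrix(FALSE, 40, 40); small[15:25, 15:25] <- TRUE
  ab <- new("ArchImage", mask = big, spacing = c(1, 1), origin = c(-20, -20),
            reference = c(0, 0), canines = rbind(c(-3, 0), c(3, 0)))
  as <- new("ArchImage", mask = small, spacing = c(1, 1),
            origin = c(-20, -20), reference = c(0, 0),
            canines = rbind(c(-3, 0), c(3, 0)))
  sup <- superimposeArches(list(ab, as))
  for (target in c(sum(big), sum(small), (sum(big) + sum(small)) / 2)) {
    got <- areaMatchedThreshold(sup, individualAreas = c(target, target))
    cand <- seq(0.01, 1, by = 0.01)
    areas <- vapply(cand, function(t) sum(sup@freq >= t), numeric(1))
    err <- abs(areas - target)
    ties <- which(err <= min(err) + 1e-12)
    want <- cand[ties][order(abs(cand[ties] - 0.5), cand[ties])][1]
    expect_equal(got@threshold, want)
  }
  ## monotone: area is non-increasing in the threshold
  areas <- vapply(seq(0.01, 1, 0.01),
                  function(t) sum(sup@freq >= t), numeric(1))
  expect_true(all(diff(areas) <= 0))
  empty <- sup; empty@freq <- matrix(0, 4, 4)
  expect_error(areaMatchedThreshold(empty), "empty")
})

test_that("centerlines of simple bands are their mid-lines", {
  ## axis-aligned rectangle band
  m <- matrix(FALSE, 60, 21); m[6:55, 6:16] <- TRUE
  cl <- archCenterline(m)
  mid <- cl[cl[, 1] > 12 & cl[, 1] < 52, 2]
  expect_lte(max(abs(mid - 10)), 1)
  ## half-annulus: centerline at the mid radius
  ann <- halfAnnulus()
  cl2 <- archCenterline(ann$mask@data, spacing = ann$mask@spacing,
                        origin = ann$mask@origin)
  r <- sqrt(rowSums(cl2^2))
  keep <- abs(atan2(cl2[, 2], cl2[, 1]) - pi / 2) < 1.2  # away from the cut ends
  expect_lt(sqrt(mean((r[keep] - ann$rc)^2)), 0.5)
  ## order: right end first
  expect_lt(cl2[1, 1], cl2[nrow(cl2), 1])
  ## disconnected masks are refused
  m2 <- matrix(FALSE, 20, 20); m2[2:5, 2:5] <- TRUE; m2[15:18, 15:18] <- TRUE
  expect_error(archCenterline(m2), "disconnected")
})
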