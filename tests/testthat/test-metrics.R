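mk <- function(dim3, idx = NULL) {
  m <- array(0, dim3)
  if (!is.null(idx)) m[idx] <- 1
  m
}

test_that("overlap metrics count voxels correctly and honour the conventions", {
  d <- c(4L, 6L, 6L)
  gt <- mk(d); gt[2, 2:3, 2:3] <- 1           # 4 voxels
  pr <- mk(d); pr[2, 2:3, 2] <- 1             # 2 voxels, both inside gt
  expect_equal(diceScore(gt, pr), 2 * 2 / (4 + 2), tolerance = 1e-12)
  expect_equal(diceScore(gt, gt), 1)
  expect_equal(diceScore(pr, mk(d, c(60, 61))), 0) # disjoint
  expect_equal(diceScore(mk(d), mk(d)), 1)         # both empty

  gt2 <- mk(d); gt2[1, 1:4, 1] <- 1                # 4 voxels
  pr2 <- mk(d); pr2[1, 1:3, 1] <- 1; pr2[3, 1:5, 3] <- 1 # hits 3 + 5 extras
  expect_equal(recallScore(gt2, pr2), 0.75)
  expect_equal(precisionScore(gt2, pr2), 0.375)
  expect_equal(recallScore(gt2, mk(d)), 0)
  expect_equal(precisionScore(gt2, mk(d)), 0)
  expect_equal(recallScore(mk(d), pr2), 0)
  expect_error(diceScore(gt, mk(c(4L, 6L, 5L))), "grid")
  # dice = 2 P R / (P + R)
  p <- precisionScore(gt2, pr2); r <- recallScore(gt2, pr2)
  expect_equal(diceScore(gt2, pr2), 2 * p * r / (p + r), tolerance = 1e-12)
})

test_that("surface extraction returns border voxel centres in mm", {
  d <- c(5L, 5L, 5L)
  single <- mk(d); single[3, 3, 3] <- 1
  sv <- surfaceVoxels(single, c(2, 1, 1))
  expect_identical(nrow(sv), 1L)
  expect_equal(as.numeric(sv), c(4, 2, 2)) # (z, y, x) = (2*2, 2*1, 2*1)
  cube <- mk(d); cube[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(surfaceVoxels(cube, c(1, 1, 1))), 26L)
  expect_identical(nrow(surfaceVoxels(mk(d), c(1, 1, 1))), 0L)
})

test_that("surface distances evaluate their hand-derived examples", {
  d <- c(4L, 8L, 8L)
  a <- mk(d); a[2, 4, 2] <- 1
  b <- mk(d); b[2, 4, 6] <- 1 # 4 voxels along x at 0.5 mm
  sp <- c(3, 0.5, 0.5)
  expect_equal(hausdorffMM(a, b, sp), 2.0, tolerance = 1e-12)
  expect_equal(hausdorffMM(a, a, sp), 0)
  expect_equal(asdMM(a, a, sp), 0)
  expect_identical(hausdorffMM(a, mk(d), sp), Inf)
  expect_identical(asdMM(mk(d), a, sp), Inf)
  expect_equal(hausdorffMM(mk(d), mk(d), sp), 0)
  # two parallel single-voxel-thick slabs, faces 2 mm apart
  s1 <- mk(d); s1[, 2, ] <- 1
  s2 <- mk(d); s2[, 6, ] <- 1
  expect_equal(asdMM(s1, s2, c(3, 0.5, 0.5)), 2.0, tolerance = 1e-12)
  # symmetry
  expect_equal(hausdorffMM(a, b, sp), hausdorffMM(b, a, sp))
  expect_equal(asdMM(s1, s2, sp), asdMM(s2, s1, sp))
})

test_that("distance metrics agree with brute-force all-pairs computation", {
  set.seed(31)
  for (trial in 1:60) {
    d <- c(8L, 12L, 12L)
    gt <- randomMask(d, stats::runif(1, 0.03, 0.3))
    pr <- randomMask(d, stats::runif(1, 0.03, 0.3))
    sp <- c(stats::runif(1, 0.5, 3), stats::runif(1, 0.3, 1.5),
            stats::runif(1, 0.3, 1.5))
    ref <- bruteSurfaceStats(gt, pr, sp)
    hd <- hausdorffMM(gt, pr, sp); as <- asdMM(gt, pr, sp)
    if (is.finite(ref$hd)) {
      expect_lt(abs(hd - ref$hd), 1e-9)
      expect_lt(abs(as - ref$asd), 1e-9)
    } else {
      expect_identical(hd, ref$hd)
      expect_identical(as, ref$asd)
    }
  }
})

test_that("distances scale with spacing while overlaps are invariant", {
  set.seed(32)
  d <- c(6L, 10L, 10L)
  gt <- randomMask(d, 0.2); pr <- randomMask(d, 0.2)
  sp <- c(2, 0.7, 0.7)
  expect_equal(hausdorffMM(gt, pr, 2 * sp), 2 * hausdorffMM(gt, pr, sp),
               tolerance = 1e-12)
  expect_equal(asdMM(gt, pr, 2 * sp), 2 * asdMM(gt, pr, sp),
               tolerance = 1e-12)
  expect_equal(lesionAxialDiameter(gt, 2 * sp), 2 * lesionAxialDiameter(gt, sp),
               tolerance = 1e-12)
  expect_identical(diceScore(gt, pr), diceScore(gt, pr))
})

test_that("axial diameters use in-plane Feret measure per component", {
  d <- c(4L, 40L, 40L)
  single <- mk(d); single[2, 5, 5] <- 1
  expect_equal(lesionAxialDiameter(single, c(3, 0.5, 0.5)), 0)
  row31 <- mk(d); row31[2, 5, 5:35] <- 1 # 31 collinear voxels at 0.5 mm
  expect_equal(lesionAxialDiameter(row31, c(3, 0.5, 0.5)), 15.0,
               tolerance = 1e-12)
  two <- mk(d)
  two[1, 2, 2:6] <- 1                     # diameter 4 mm at 1 mm pitch
  two[4, 20, 10:30] <- 1                  # diameter 20 mm
  expect_equal(lesionAxialDiameter(two, c(3, 1, 1)), 20.0, tolerance = 1e-12)
  expect_equal(lesionAxialDiameter(mk(d), c(3, 1, 1)), 0)
  # a diagonal component measured via brute-force pairwise distances
  set.seed(33)
  blob <- mk(c(3L, 12L, 12L))
  sl <- blob[2, , ]
  p <- c(6L, 6L) # connected random walk stays one 26-component
  for (step in 1:20) {
    sl[p[1], p[2]] <- 1
    p <- pmin(pmax(p + sample(c(-1L, 0L, 1L), 2, TRUE), 2L), 11L)
  }
  blob[2, , ] <- sl
  idx <- which(blob[2, , ] == 1, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, c(0.8, 0.6), `*`)
  expect_equal(lesionAxialDiameter(blob, c(3, 0.8, 0.6)),
               max(stats::dist(pts)), tolerance = 1e-12)
})

test_that("stratification applies the half-open 15 mm and 30 mm boundaries", {
  expect_identical(stratifyDiameter(14.9), "0-15")
  expect_identical(stratifyDiameter(15.0), "15-30")
  expect_identical(stratifyDiameter(30.0), "15-30")
  expect_identical(stratifyDiameter(30.1), ">30")
  expect_identical(stratifyDiameter(0), "0-15")
  expect_error(stratifyDiameter(-1), "non-negative")
})

test_that("aggregation uses means, medians and survives infinite distances", {
  d <- c(4L, 10L, 10L)
  gt <- mk(d); gt[2, 3:6, 3:6] <- 1
  one <- caseMetrics(gt, gt, c(3, 1, 1), id = "self")
  rep1 <- aggregateMetrics(one)
  ov <- rep1[rep1$stratum == "overall", ]
  expect_equal(ov$dice_mean, 1)
  expect_equal(ov$hausdorff_median, 0)

  cases <- data.frame(id = c("a", "b", "c"),
                      dice = c(0.2, 0.4, 0.6),
                      hausdorff_mm = c(1.0, 2.0, Inf),
                      asd_mm = c(0.5, 1.5, Inf),
                      recall = c(0.1, 0.2, 0.3),
                      precision = c(0.3, 0.2, 0.1),
                      lesion_diameter_mm = c(10, 20, 40),
                      stratum = c("0-15", "15-30", ">30"))
  rep3 <- aggregateMetrics(cases)
  ov <- rep3[rep3$stratum == "overall", ]
  expect_equal(ov$hausdorff_median, 2.0) # finite despite an empty prediction
  expect_equal(ov$dice_mean, 0.4, tolerance = 1e-12)
  expect_identical(ov$n, 3L)
  expect_identical(sum(rep3$n[rep3$stratum != "overall"]), 3L)
  expect_error(aggregateMetrics(cases[0, ]), "nonempty")
})
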