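test_that("resampling reproduces the factor-2 in-plane geometry", {
  v <- ImageVolume(array(stats::rnorm(12 * 96 * 96), c(12, 96, 96)), c(3, 1, 1))
  out <- resampleToSpacing(v, c(3, 0.5, 0.5))
  expect_identical(dim(voxelValues(out)), c(12L, 192L, 192L))
  expect_identical(spacingMM(out), c(3, 0.5, 0.5))
})

test_that("resampling a constant volume returns the same constant", {
  v <- ImageVolume(array(4.2, c(6, 20, 20)), c(3, 1, 1))
  out <- resampleToSpacing(v, c(2, 0.7, 0.7))
  expect_true(all(abs(voxelValues(out) - 4.2) < 1e-12))
})

test_that("masks stay binary through resampling", {
  set.seed(1)
  m <- ImageVolume(randomMask(c(6, 20, 20), 0.3), c(3, 1, 1), mask = TRUE)
  out <- resampleToSpacing(m, c(2, 0.6, 0.6))
  expect_true(all(voxelValues(out) %in% c(0, 1)))
  expect_true(isMask(out))
  expect_error(resampleToSpacing(m, c(0, 1, 1)), "positive")
})

test_that("whole-gland masking zeroes exactly the voxels outside the gland", {
  img <- ImageVolume(array(1, c(4, 5, 6)), c(1, 1, 1))
  ones <- ImageVolume(array(1, c(4, 5, 6)), c(1, 1, 1), mask = TRUE)
  zeros <- ImageVolume(array(0, c(4, 5, 6)), c(1, 1, 1), mask = TRUE)
  expect_identical(voxelValues(applyWgMask(img, ones)), voxelValues(img))
  expect_true(all(voxelValues(applyWgMask(img, zeros)) == 0))
  set.seed(2)
  wg <- ImageVolume(randomMask(c(4, 5, 6), 0.4), c(1, 1, 1), mask = TRUE)
  expect_equal(sum(voxelValues(applyWgMask(img, wg))), sum(voxelValues(wg)))
  small <- ImageVolume(array(1, c(3, 5, 6)), c(1, 1, 1), mask = TRUE)
  expect_error(applyWgMask(img, small), "grid")
})

test_that("crop-or-pad reaches the target shape and preserves content", {
  set.seed(3)
  v <- ImageVolume(array(stats::rnorm(30 * 256 * 256), c(30, 256, 256)),
                   c(3, 0.5, 0.5))
  out <- cropOrPad(v, c(24L, 192L, 192L))
  expect_identical(dim(voxelValues(out)), c(24L, 192L, 192L))
  # central window unchanged
  expect_identical(voxelValues(out)[1, 1, 1], voxelValues(v)[4, 33, 33])

  same <- cropOrPad(out, c(24L, 192L, 192L))
  expect_identical(voxelValues(same), voxelValues(out))

  ones <- ImageVolume(array(1, c(20, 128, 128)), c(3, 0.5, 0.5))
  padded <- cropOrPad(ones, c(24L, 192L, 192L))
  expect_equal(sum(voxelValues(padded)), 20 * 128 * 128)
  # symmetric pad, extra voxel on the high-index side
  odd <- cropOrPad(ImageVolume(array(1, c(5, 4, 4)), c(1, 1, 1)), c(8L, 4L, 4L))
  expect_equal(apply(voxelValues(odd), 1, sum), c(0, 16, 16, 16, 16, 16, 0, 0))
})

test_that("min-max normalisation follows the formula and its degenerate rule", {
  v <- ImageVolume(array(seq(10, 1010, length.out = 4 * 4 * 4), c(4, 4, 4)),
                   c(1, 1, 1))
  out <- minmaxNormalize(v)
  expect_equal(voxelValues(out), (voxelValues(v) - 10) / 1000, tolerance = 1e-12)
  flat <- minmaxNormalize(ImageVolume(array(7, c(3, 3, 3)), c(1, 1, 1)))
  expect_true(all(voxelValues(flat) == 0))
  unitv <- ImageVolume(array(c(0, 1, stats::runif(25)), c(3, 3, 3)), c(1, 1, 1))
  expect_equal(voxelValues(minmaxNormalize(unitv)), voxelValues(unitv))
  m <- ImageVolume(array(1, c(2, 2, 2)), c(1, 1, 1), mask = TRUE)
  expect_error(minmaxNormalize(m), "mask")
})

test_that("the full pipeline yields the fixed-geometry tensor and clean label", {
  case <- generateCase(tinySpec(seed = 21L, noise = 0.05))
  mi <- preprocessCase(case, PreprocessConfig())
  expect_identical(dim(inputTensor(mi)), c(24L, 192L, 192L, 3L))
  expect_identical(dim(inputLabel(mi)), c(24L, 192L, 192L))
  expect_true(all(inputTensor(mi) >= 0 & inputTensor(mi) <= 1))
  expect_true(all(inputLabel(mi) %in% c(0, 1)))
  expect_gt(sum(inputLabel(mi)), 0)
})

test_that("a case with an empty lesion mask preprocesses to an all-zero label", {
  case <- generateCase(tinySpec(seed = 22L))
  empty <- ImageVolume(array(0, dim(voxelValues(lesionMask(case)))),
                       spacingMM(case), mask = TRUE)
  case2 <- ProstateCase(caseId(case), case@t2w, case@adc, case@dwi,
                        wgMask(case), empty)
  mi <- preprocessCase(case2, PreprocessConfig())
  expect_true(all(inputLabel(mi) == 0))
})

test_that("preprocessing an already-conformant case is the identity", {
  set.seed(4)
  shape <- c(8L, 24L, 24L)
  wg <- array(0, shape); wg[3:6, 6:18, 6:18] <- 1
  les <- array(0, shape); les[4:5, 10:13, 10:13] <- 1
  mk <- function(seed) {
    set.seed(seed)
    v <- array(stats::runif(prod(shape)), shape) * wg
    v <- v / max(v) # spans [0, 1]
    ImageVolume(v, c(3, 0.5, 0.5))
  }
  case <- ProstateCase("conformant", mk(5), mk(6), mk(7),
                       ImageVolume(wg, c(3, 0.5, 0.5), mask = TRUE),
                       ImageVolume(les, c(3, 0.5, 0.5), mask = TRUE))
  mi <- preprocessCase(case, PreprocessConfig(targetSpacingMM = c(3, 0.5, 0.5),
                                              targetShape = shape))
  expect_equal(inputTensor(mi)[, , , 1], voxelValues(case@t2w), tolerance = 1e-12)
  expect_equal(inputLabel(mi), les)
})

test_that("lesion diameters survive resampling within one native in-plane voxel", {
  for (s in 1:4) {
    case <- generateCase(tinySpec(seed = 200L + s,
                                  diameter = c(9, 13, 18, 24)[s]))
    before <- lesionAxialDiameter(lesionMask(case))
    mi <- preprocessCase(case, PreprocessConfig(targetShape = c(16L, 160L, 160L),
                                                targetSpacingMM = c(3, .5, .5)))
    after <- lesionAxialDiameter(inputLabel(mi), c(3, .5, .5))
    expect_lt(abs(after - before), 1.0 + 1e-9)
  }
})
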