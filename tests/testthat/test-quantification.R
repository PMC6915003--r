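test_that("ROI means follow voxel-center membership", {
  img <- voxelImage(matrix(4.2, 64, 64), 2.4)
  expect_equal(roiMean(img, roiSpec(c(0, 0), 20)), 4.2)
  # 20 mm ROI on a 2.4 mm grid includes at least 52 voxel centers,
  # agreeing with the brute-force count
  n <- oracleDiskCount(c(64L, 64L), c(2.4, 2.4), c(0, 0), 10)
  expect_gte(n, 52)
  expect_identical(sum(acval:::.roiMask(img, roiSpec(c(0, 0), 20))), n)
  # half-plane 0 | 2 with the ROI centered on the boundary averages ~1
  half <- matrix(rep(c(0, 2), each = 32), 64, 64)
  expect_equal(roiMean(voxelImage(half, 2.4), roiSpec(c(0, 0), 20)), 1,
               tolerance = 0.08)
  # errors: circle outside bounds, no voxel centers inside
  expect_error(roiMean(img, roiSpec(c(70, 0), 20)), "bounds")
  expect_error(roiMean(img, roiSpec(c(0, 0), 0.5)), "no voxel")
})

test_that("slice uniformity evaluates the max-deviation statistic", {
  expect_equal(sliceUniformity(c(1, 1, 1, 1), 1), 0)
  expect_equal(sliceUniformity(c(1.1, 1.0, 1.0, 1.0), 1.0), 0.10)
  # min branch dominates
  expect_equal(sliceUniformity(c(0.9, 1.0, 1.05, 1.0), 1.0), 0.10)
  expect_error(sliceUniformity(c(1, 1, 1, 1), 0), "positive")
  # invariant under global rescaling
  set.seed(2)
  for (k in 1:20) {
    B <- runif(4, 0.5, 1.5); A1 <- runif(1, 0.5, 1.5); s <- runif(1, 0.1, 9)
    expect_equal(sliceUniformity(B, A1), sliceUniformity(s * B, s * A1))
  }
})

test_that("whole-image uniformity is the max over slices and sees a known bump", {
  lay <- uniformityLayout()
  # 5-slice constant volume -> exactly 0
  vol <- array(2, c(128, 128, 5))
  vi <- voxelImage(vol, c(2.4, 2.4, 30), c(centeredOrigin(c(128, 128), 2.4), -60))
  u0 <- imageUniformity(vi, lay)
  expect_equal(u0@wholeImage, 0)
  expect_equal(nrow(u0@perSlice), 5L)
  # +20% exactly over one B circle in one slice -> uniformity ~0.20, diluted
  # by the bump's overlap with the central 120 mm circle (which raises A1)
  img2d <- voxelImage(vol[, , 3], c(2.4, 2.4))
  bump <- acval:::.roiMask(img2d, roiSpec(c(45, 0), 60))
  a1m <- acval:::.roiMask(img2d, roiSpec(c(0, 0), 120))
  vol[, , 3][bump] <- 2 * 1.2
  vib <- voxelImage(vol, c(2.4, 2.4, 30), c(centeredOrigin(c(128, 128), 2.4), -60))
  ub <- imageUniformity(vib, lay)
  a1 <- mean(ifelse(bump[a1m], 2.4, 2))      # diluted central mean
  expect_equal(ub@perSlice$A1[3], a1)
  expect_equal(ub@wholeImage, max(abs(2.4 - a1), abs(2 - a1)) / a1)
  expect_equal(ub@wholeImage, 0.20, tolerance = 0.25)
  # whole-image >= every slice, equality at the argmax slice
  expect_true(all(ub@wholeImage >= ub@perSlice$uniformity))
  expect_equal(ub@perSlice$uniformity[3], ub@wholeImage)
  # 2D fallback equals the single slice's uniformity
  u2d <- imageUniformity(voxelImage(vol[, , 3], c(2.4, 2.4)), lay)
  expect_equal(u2d@wholeImage, ub@perSlice$uniformity[3])
  # an offset beyond the stack is rejected
  thin <- voxelImage(vol[, , 1:2], c(2.4, 2.4, 2.85))
  expect_error(imageUniformity(thin, lay), "axial extent")
})

test_that("the 50% isocontour VOI keeps the argmax component", {
  v <- matrix(0, 16, 16)
  v[8, 8] <- 5
  region <- matrix(TRUE, 16, 16)
  m <- voiIsocontour(voxelImage(v, 1), region)
  expect_identical(which(m), which(v == 5))
  # line {10, 6, 5, 4, 2}: inclusive threshold at 5 keeps {10, 6, 5}
  v2 <- matrix(0, 16, 16)
  v2[5:9, 8] <- c(10, 6, 5, 4, 2)
  m2 <- voiIsocontour(voxelImage(v2, 1), region)
  expect_identical(which(m2), which(v2 >= 5))
  # uniform positive region -> the whole region
  v3 <- matrix(1, 16, 16)
  m3 <- voiIsocontour(voxelImage(v3, 1), region)
  expect_true(all(m3))
  # a disconnected equal-valued blob is dropped
  v4 <- matrix(0, 16, 16); v4[3, 3] <- 8; v4[12, 12] <- 6
  m4 <- voiIsocontour(voxelImage(v4, 1), region)
  expect_true(m4[3, 3]); expect_false(m4[12, 12])
  # mask size nonincreasing in the threshold fraction, argmax always kept
  for (f in c(0.2, 0.5, 0.8, 1)) {
    mf <- voiIsocontour(voxelImage(v2, 1), region, fraction = f)
    expect_true(mf[5, 8])
    if (f > 0.2) expect_lte(sum(mf), sum(mPrev))
    mPrev <- mf
  }
  expect_error(voiIsocontour(voxelImage(matrix(0, 4, 4), 1),
                             matrix(TRUE, 4, 4)), "positive")
})

test_that("SUV scaling follows dose and weight", {
  img <- voxelImage(matrix(2, 8, 8), 1)
  expect_identical(values(suvScale(img, 70, 70)), values(img))
  expect_equal(values(suvScale(img, 2 * 70, 70)), values(img) / 2)
  expect_equal(values(suvScale(img, 310.8, 70))[1, 1], 2 * 70 / 310.8)
  expect_error(suvScale(img, 0, 70), "positive")
  st <- voiStats(img, matrix(TRUE, 8, 8))
  expect_gte(st[["max"]], st[["mean"]])
})
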