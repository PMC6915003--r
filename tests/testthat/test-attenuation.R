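test_that("bilinear HU conversion hits air, water and bone", {
  hu <- voxelImage(matrix(c(-1000, 0, 1000, -500), 2, 2), 2.4)
  lac <- values(huToLac(hu))
  expect_equal(lac[1, 1], 0)
  expect_equal(lac[2, 1], 0.0096)
  expect_equal(lac[1, 2], 0.0147)       # 0.0096 + 5.1e-6 * 1000
  expect_equal(lac[2, 2], 0.0048)
  # monotone nondecreasing in HU
  set.seed(11)
  h <- sort(runif(200, -1024, 2000))
  out <- values(huToLac(voxelImage(matrix(h, 200, 1), 1)))
  expect_true(all(diff(out) >= 0))
  expect_error(huToLac(voxelImage(matrix(NaN, 1, 1), 1)), "finite")
  expect_error(huToLac(voxelImage(matrix(-1100, 1, 1), 1)), "-1024")
})

test_that("synthesized CT inverts the conversion on every tissue class", {
  g <- imageGrid(128, 2.4)
  ph <- makeBodyPhantom(phantomSpec("body_slice"), g)
  ct <- synthCtFromLabels(ph$labels)
  hu <- values(ct)
  expect_equal(unique(hu[labelMask(ph$labels, "air")]), -1000)
  # bone HU from inverting the bone branch: (0.0161-0.0096)/5.1e-6
  expect_equal(unique(hu[labelMask(ph$labels, "bone")]), 1274.5098,
               tolerance = 1e-6)
  # round trip: huToLac o synthCt == ground truth to 1e-6 mm^-1
  back <- values(huToLac(ct))
  expect_lt(max(abs(back - values(lacImage(ph$labels)))), 1e-6)
  # seeded CT noise is reproducible and sized as requested
  n1 <- synthCtFromLabels(ph$labels, noiseSdHu = 20, seed = 5)
  n2 <- synthCtFromLabels(ph$labels, noiseSdHu = 20, seed = 5)
  expect_identical(values(n1), values(n2))
  unclipped <- hu > -999  # air noise is floored at -1000 HU
  expect_equal(sd((values(n1) - hu)[unclipped]), 20, tolerance = 0.05)
})

test_that("segmented-CT binning reproduces every bin assignment and endpoint", {
  # sweep spanning all bins plus both printed endpoints
  lac <- c(0, 0.002, 0.0029, 0.003, 0.005, 0.0089, 0.009, 0.010,
           0.0109, 0.011, 0.0161, 0.020, 0.030)
  want <- c(0, 0, 0, 0.008, 0.008, 0.008, 0.0096, 0.0096,
            0.0096, 0.0161, 0.0161, 0.0161, 0.0161)
  mu <- muMap(matrix(lac, length(lac), 1), 1)
  seg <- segmentCtLac(mu)
  expect_equal(as.vector(values(seg)), want)
  # lung override wins over any bin
  lung <- matrix(FALSE, length(lac), 1); lung[12, 1] <- TRUE
  seg2 <- segmentCtLac(mu, lung)
  expect_equal(values(seg2)[12, 1], 0.0032)
  # output contains only the five assigned values
  expect_true(all(values(seg2) %in% c(0, 0.008, 0.0096, 0.0161, 0.0032)))
})

test_that("segmentation is idempotent and monotone for non-lung voxels", {
  set.seed(3)
  v <- matrix(runif(400, 0, 0.025), 20, 20)
  lung <- matrix(runif(400) < 0.2, 20, 20)
  mu <- muMap(v, 2.4)
  s1 <- segmentCtLac(mu, lung)
  s2 <- segmentCtLac(s1, lung)
  expect_identical(values(s1), values(s2))
  # monotone nondecreasing in input LAC off the lung mask
  o <- order(v[!lung])
  segged <- values(s1)[!lung]
  expect_true(all(diff(segged[o]) >= 0))
  expect_error(segmentCtLac(mu, matrix(FALSE, 3, 3)), "grid")
})

test_that("segmentation rules reject inconsistent thresholds or values", {
  expect_error(lacSegmentationRule(thresholds = c(air = 0.01, fat = 0.009,
                                                  water = 0.011)),
               "strictly increasing")
  expect_error(lacSegmentationRule(
    assigned = c(air = 0, fat = 0.01, water = 0.0096, bone = 0.0161,
                 lung = 0.0032)),
    "inside their own bins")
})

test_that("MRAC mu-map collapses bone to soft tissue and caps patient LAC", {
  g <- imageGrid(128, 2.4)
  ph <- makeBodyPhantom(phantomSpec("body_slice"), g)
  mu <- mracMuMap(ph$labels)
  v <- values(mu)
  expect_true(all(v[labelMask(ph$labels, "bone")] == 0.0096))
  expect_true(all(v[labelMask(ph$labels, "fat")] == 0.0080))
  expect_true(all(v[labelMask(ph$labels, "lung")] == 0.0032))
  expect_true(all(v[labelMask(ph$labels, "air")] == 0))
  expect_lte(max(v), 0.0096)  # never exceeds soft tissue in patient tissue
  expect_identical(provenance(mu), "mrac")
  # all-air label map -> all-zero mu-map
  ph0 <- makeCylinderPhantom(phantomSpec("cylinder", diameterMm = 0),
                             smallGrid())
  expect_true(all(values(mracMuMap(ph0$labels)) == 0))
})

test_that("hardware is composited into MRAC only on request", {
  g <- imageGrid(128, 2.4)
  lab <- makeCylinderPhantom(
    phantomSpec("cylinder", diameterMm = 100,
                hardwareConfig = "track+bed"), g)$labels
  expect_error(mracMuMap(lab, includeHardware = TRUE), "hardware mu-map")
  hw <- hardwareMuMap(lab)
  withHw <- mracMuMap(lab, includeHardware = TRUE, hardwareMu = hw)
  without <- mracMuMap(lab)
  hwMask <- values(hw) > 0
  expect_true(all(values(withHw)[hwMask] == values(hw)[hwMask]))
  expect_true(all(values(without)[hwMask] == 0))
  expect_identical(provenance(without), "mrac_no_hardware")
  expect_identical(values(completeTruncation(withHw)), values(withHw))
})
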