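# Shared noiseless disk fixture: 128 x 128 at 2.4 mm, true-mu AC.
.diskFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- imageGrid(128, 2.4)
      ph <- makeCylinderPhantom(phantomSpec("cylinder"), g)
      mu <- lacImage(ph$labels)
      geo <- projectionGeometry(g, nAngles = 120)
      sino <- simulateEmission(ph$activity, mu, geo, totalCounts = NULL,
                               poisson = FALSE)
      cache <<- list(g = g, ph = ph, mu = mu, geo = geo, sino = sino)
    }
    cache
  }
})

test_that("an all-zero sinogram reconstructs to an all-zero image", {
  f <- .diskFixture()
  zero <- new("Sinogram", counts = 0 * counts(f$sino),
              attenuationFactors = attenuationOf(f$sino),
              geometry = f$geo, scale = 0)
  rec <- osemReconstruct(zero, f$mu, reconParams(20, 1, 0))
  expect_true(all(values(rec) == 0))
})

test_that("OSEM with true-mu AC recovers a uniform disk within 5%", {
  f <- .diskFixture()
  rec <- osemReconstruct(f$sino, f$mu, reconParams(20, 3, 3))
  ctr <- roiMean(rec, roiSpec(c(0, 0), 60))
  expect_equal(ctr, 1, tolerance = 0.05)  # true activity is 1
})

test_that("true activity is an MLEM fixed point under noiseless data", {
  f <- .diskFixture()
  rec <- osemReconstruct(f$sino, f$mu, reconParams(1, 1, 0),
                         init = f$ph$activity)
  v0 <- values(f$ph$activity)
  nz <- v0 > 0
  expect_lt(max(abs(values(rec)[nz] / v0[nz] - 1)), 1e-6)
})

test_that("unfiltered MLEM matches measured total counts after convergence", {
  g <- imageGrid(64, 4.8)
  ph <- makeCylinderPhantom(phantomSpec("cylinder"), g)
  mu <- lacImage(ph$labels)
  geo <- projectionGeometry(g, nAngles = 60)
  sino <- simulateEmission(ph$activity, mu, geo, totalCounts = NULL,
                           poisson = FALSE)
  rec <- osemReconstruct(sino, mu, reconParams(1, 40, 0))
  fwd <- attenuationOf(sino) * lineIntegrals(rec, geo)
  expect_equal(sum(fwd), sum(counts(sino)), tolerance = 1e-3)
})

test_that("reconstruction is deterministic and rejects bad configurations", {
  f <- .diskFixture()
  p <- reconParams(20, 1, 3)
  r1 <- osemReconstruct(f$sino, f$mu, p)
  r2 <- osemReconstruct(f$sino, f$mu, p)
  expect_identical(values(r1), values(r2))
  expect_error(osemReconstruct(f$sino, f$mu, reconParams(500, 1, 0)),
               "subsets")
})

test_that("understated AC mu lowers the reconstructed value in that region", {
  # bone-insert disk: the MRAC-style map assigns soft-tissue mu to bone
  g <- imageGrid(128, 2.4)
  ph <- makeCylinderPhantom(phantomSpec("cylinder"), g)
  ins <- ph$labels
  codes <- ins@labels
  org <- origin(ph$activity); sp <- spacing(ph$activity)
  x <- org[1] + (seq_len(128) - 1) * sp[1]
  y <- org[2] + (seq_len(128) - 1) * sp[2]
  insert <- outer(x - 40, y, function(a, b) a^2 + b^2 <= 20^2)
  codes[insert] <- match("bone", ins@classes)
  ins@labels <- codes
  muTrue <- lacImage(ins)
  muUnder <- mracMuMap(ins)   # bone -> 0.0096 < true 0.0161
  geo <- projectionGeometry(g, nAngles = 120)
  sino <- simulateEmission(ph$activity, muTrue, geo, totalCounts = NULL,
                           poisson = FALSE)
  recTrue <- osemReconstruct(sino, muTrue, reconParams(20, 3, 3))
  recUnder <- osemReconstruct(sino, muUnder, reconParams(20, 3, 3))
  roi <- roiSpec(c(40, 0), 30)
  expect_lt(roiMean(recUnder, roi), roiMean(recTrue, roi))
})

test_that("monotone AC response: a uniformly scaled-up AC map raises ROI means", {
  f <- .diskFixture()
  up <- muMap(values(f$mu) * 1.1, spacing(f$mu), origin(f$mu), "custom")
  down <- muMap(values(f$mu) * 0.9, spacing(f$mu), origin(f$mu), "custom")
  p <- reconParams(20, 2, 3)
  rUp <- osemReconstruct(f$sino, up, p)
  r0 <- osemReconstruct(f$sino, f$mu, p)
  rDn <- osemReconstruct(f$sino, down, p)
  for (cc in list(c(0, 0), c(50, 0), c(0, -50))) {
    roi <- roiSpec(cc, 30)
    expect_gt(roiMean(rUp, roi), roiMean(r0, roi))
    expect_lt(roiMean(rDn, roi), roiMean(r0, roi))
  }
})

test_that("the Gaussian post-filter preserves mass, constants and peak shape", {
  img <- voxelImage(matrix(0, 65, 65), 2.4)
  expect_identical(values(gaussianPostFilter(img, 0)), values(img))
  # constant image unchanged (edge-normalized)
  cst <- voxelImage(matrix(3.7, 40, 40), 2.4)
  expect_equal(values(gaussianPostFilter(cst, 3)), values(cst))
  # delta response: peak ~ 1/(2 pi sigma_px^2), sum preserved
  v <- matrix(0, 65, 65); v[33, 33] <- 1
  blur <- values(gaussianPostFilter(voxelImage(v, 2.4), 3))
  sigmaPx <- 3 / (2 * sqrt(2 * log(2))) / 2.4
  expect_equal(blur[33, 33], 1 / (2 * pi * sigmaPx^2), tolerance = 0.05)
  expect_equal(sum(blur), 1, tolerance = 1e-6)
  expect_error(gaussianPostFilter(voxelImage(v, 2.4), -1), ">= 0")
})
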