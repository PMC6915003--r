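test_that("cylinder phantom matches brute-force voxelization and conserves activity", {
  g <- imageGrid(256, 2.4)
  ph <- makeCylinderPhantom(phantomSpec("cylinder"), g, activityValue = 2.5)
  inside <- values(ph$activity) > 0
  expected <- oracleDiskCount(g$n, g$spacing, c(0, 0), 100)
  expect_identical(sum(inside), expected)
  # analytic area pi * (100/2.4)^2 ~ 5454, voxelization within ~1%
  expect_lt(abs(sum(inside) - pi * (100 / 2.4)^2), 60)
  # labels: interior soft, exterior air
  expect_true(all(values(lacImage(ph$labels))[inside] ==
                  tissueLacTable()[["soft"]]))
  expect_identical(sum(labelMask(ph$labels, "soft")), expected)
  # total activity = constant x voxel count x voxel volume
  vol <- prod(g$spacing)
  expect_equal(sum(values(ph$activity)) * vol, 2.5 * expected * vol)
})

test_that("degenerate and oversized cylinders are handled", {
  g <- smallGrid()
  ph0 <- makeCylinderPhantom(phantomSpec("cylinder", diameterMm = 0), g)
  expect_true(all(values(ph0$activity) == 0))
  expect_true(all(labelMask(ph0$labels, "air")))
  expect_error(
    makeCylinderPhantom(phantomSpec("cylinder", diameterMm = 400), g),
    "exceeds the grid")
})

test_that("hardware configurations are cumulative, zero-activity and attenuating", {
  g <- imageGrid(256, 2.4)
  base <- makeCylinderPhantom(phantomSpec("cylinder"), g)$labels
  expect_identical(addHardware(base, "none")@labels, base@labels)
  nHw <- vapply(hardwareConfigs(), function(cfg) {
    lab <- addHardware(base, cfg)
    sum(grepl("^hardware_", lab@classes[lab@labels]))
  }, numeric(1))
  expect_true(all(diff(nHw) > 0))  # each config strictly grows
  # activity is zero wherever hardware (or air) sits
  full <- makeCylinderPhantom(
    phantomSpec("cylinder", hardwareConfig = "track+bed+spine+head_full"), g)
  hw <- grepl("^hardware_", full$labels@classes[full$labels@labels])
  expect_true(all(values(full$activity)[hw] == 0))
  expect_true(all(values(full$activity)[labelMask(full$labels, "air")] == 0))
  # vertical mu line integral through the center grows with full hardware
  geo <- projectionGeometry(g, nAngles = 2)  # angles 0 and pi/2
  i0 <- which.min(abs(geo@sCenters))
  muNone <- lineIntegrals(lacImage(base), geo)
  muFull <- lineIntegrals(lacImage(full$labels), geo)
  expect_gt(muFull[1, i0], muNone[1, i0])
})

test_that("ground-truth LAC ordering holds", {
  lac <- tissueLacTable()
  expect_identical(unname(lac[["air"]]), 0)
  expect_true(lac[["bone"]] > lac[["soft"]] &&
              lac[["soft"]] > lac[["fat"]] &&
              lac[["fat"]] > lac[["lung"]] && lac[["lung"]] > 0)
})

test_that("body phantom has the required compartments and is reproducible", {
  g <- imageGrid(128, 2.4)
  ph <- makeBodyPhantom(phantomSpec("body_slice"), g)
  # exactly one connected component per lung region
  lung <- EBImage::bwlabel(labelMask(ph$labels, "lung"))
  expect_equal(max(lung), 2)
  for (cls in c("lung", "fat", "soft", "bone", "lesion_soft", "lesion_bone",
                "liver"))
    expect_gt(sum(labelMask(ph$labels, cls)), 0)
  # lesion uptake at least 2x local background
  act <- values(ph$activity)
  expect_gte(min(act[labelMask(ph$labels, "lesion_soft")]),
             2 * tissueUptakeTable()[["soft"]])
  # seeded generation is bitwise reproducible
  sp <- phantomSpec("body_slice", seed = 42L, randomLesions = TRUE)
  a <- makeBodyPhantom(sp, g); b <- makeBodyPhantom(sp, g)
  expect_identical(values(a$activity), values(b$activity))
  expect_identical(a$labels@labels, b$labels@labels)
  expect_identical(a$lesions, b$lesions)
})

test_that("the isocontour VOI recovers a lesion from ground-truth activity", {
  g <- imageGrid(128, 2.4)
  les <- data.frame(x = -60, y = -20, radiusMm = 8, uptake = 4,
                    type = "lesion_soft", stringsAsFactors = FALSE)
  ph <- makeBodyPhantom(phantomSpec("body_slice", lesions = les), g)
  mask <- voiIsocontour(ph$activity, roiSpec(c(-60, -20), 32))
  ctr <- round((c(-60, -20) - origin(ph$activity)[1:2]) /
               spacing(ph$activity)[1:2]) + 1
  expect_true(mask[ctr[1], ctr[2]])
})

test_that("incompatible lesion placement is rejected", {
  g <- imageGrid(128, 2.4)
  les <- data.frame(x = 60, y = 25, radiusMm = 8, uptake = 4,
                    type = "lesion_soft", stringsAsFactors = FALSE)  # in lung
  expect_error(makeBodyPhantom(phantomSpec("body_slice", lesions = les), g),
               "incompatible")
})

test_that("phantom specs round-trip through YAML and JSON", {
  sp <- phantomSpec("body_slice", seed = 7L, randomLesions = TRUE)
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("spec.", ext))
    writePhantomSpec(sp, f)
    sp2 <- readPhantomSpec(f)
    expect_identical(sp2@kind, sp@kind)
    expect_identical(sp2@seed, sp@seed)
    expect_identical(sp2@randomLesions, sp@randomLesions)
  }
})
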