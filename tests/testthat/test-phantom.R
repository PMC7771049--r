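test_that("phantom generation is bit-reproducible for a given seed", {
  a <- generatePhantom(seed = 42, volumes = FALSE)
  b <- generatePhantom(seed = 42, volumes = FALSE)
  expect_identical(a@tree@nodes, b@tree@nodes)
  expect_identical(junctions(a@tree), junctions(b@tree))
  expect_identical(a@truth$angles, b@truth$angles)
  c <- generatePhantom(seed = 43, volumes = FALSE)
  expect_false(identical(junctions(a@tree), junctions(c@tree)))
})

test_that("rasterized phantoms are bit-reproducible and well-formed", {
  cfg <- smallPhantomConfig()
  a <- generatePhantom(cfg, seed = 7, volumes = TRUE)
  b <- generatePhantom(cfg, seed = 7, volumes = TRUE)
  expect_identical(voxelValues(a@structural), voxelValues(b@structural))
  expect_identical(voxelValues(a@angiographic), voxelValues(b@angiographic))
  expect_identical(maskArray(a@cortexMask), maskArray(b@cortexMask))
  expect_gt(maskCount(a@cortexMask), 0)
  expect_equal(modality(a@angiographic), "angiographic")
})

test_that("fixed counts are honored exactly", {
  cfg <- phantomConfig(countMeans = matrix(c(4, 4, 3, 4, 4, 3), nrow = 2,
                                           byrow = TRUE,
                                           dimnames = list(c("L", "R"),
                                             c("frontal", "middle",
                                               "occipital"))),
                       fixedCounts = TRUE)
  ph <- generatePhantom(cfg, seed = 3, volumes = FALSE)
  cnt <- countBridgingVeins(ph@tree, ph@sinus)
  expect_equal(unname(cnt$side_totals), c(11, 11))
  expect_equal(unname(cnt$table["L", ]), c(4, 4, 3))
})

test_that("every generated angle lies inside its group's anatomical range", {
  cfg <- phantomConfig()
  for (s in 1:10) {
    ph <- generatePhantom(cfg, seed = 100 + s, volumes = FALSE)
    tr <- ph@truth$angles
    gi <- match(tr$group, angleGroups)
    expect_true(all(tr$angle >= cfg@angleRanges[gi, 1] &
                    tr$angle <= cfg@angleRanges[gi, 2]))
  }
})

test_that("the default threshold segments nearly all tube centerline voxels", {
  cfg <- smallPhantomConfig()
  ph <- generatePhantom(cfg, seed = 5, volumes = TRUE)
  lab <- voxelValues(ph@angiographic) > ph@truth$threshold
  g <- ph@angiographic@grid
  ctr <- do.call(rbind, lapply(veinfuse:::veinPolylines(ph@tree),
                               veinfuse:::resamplePolyline, step = 1))
  ctr <- rbind(ctr, veinfuse:::resamplePolyline(ph@sinus@centerline, 1))
  idx <- round(sweep(sweep(ctr, 2, worldOrigin(g)), 2, spacing(g), `/`)) + 1
  sh <- gridShape(g)
  ok <- idx[, 1] >= 1 & idx[, 1] <= sh[1] & idx[, 2] >= 1 &
        idx[, 2] <= sh[2] & idx[, 3] >= 1 & idx[, 3] <= sh[3]
  expect_gte(mean(lab[idx[ok, , drop = FALSE]]), 0.99)
})

test_that("registration trial generation honors sigma and n", {
  gold <- RigidParams(1, 2, 3, 4, 5, 6)
  ts0 <- generateRegistrationTrials(gold, 0, 0, n = 4, seed = 1)
  expect_length(trials(ts0), 4)
  for (tr in trials(ts0)) expect_equalParams(tr, gold)

  ts <- generateRegistrationTrials(gold, sigmaT = 0.5, sigmaR = 0.3,
                                   n = 10, seed = 2)
  expect_length(trials(ts), 10)
  mask <- shellMask(c(11, 11, 11), c(1.5, 1.5, 1.5), 6, 3)
  err <- mcSpatialError(trials(ts)[[1]], gold, mask, 500, seed = 3)
  expect_gt(err, 0)
  expect_identical(
    lapply(trials(generateRegistrationTrials(gold, 0.5, 0.3, 5, seed = 9)),
           translation),
    lapply(trials(generateRegistrationTrials(gold, 0.5, 0.3, 5, seed = 9)),
           translation))
})

test_that("confounder-free photos close the loop at 100% Category 0", {
  ph <- generatePhantom(seed = 21, volumes = FALSE)
  cfg <- phantomConfig(photoDropout = 0, photoExtraRate = 0,
                       arteryCount = 0, occlusionCount = 0, jitterSD = 0,
                       misalignment = Similarity2D())
  b <- generatePhoto(ph, config = cfg, seed = 22)
  v <- runValidation(b, tol = 3)
  expect_true(all(v$classification$category == 0))
  expect_equal(unname(categoryPercentages(v$summary)[1]), 100)
  expect_equal(categoryRecovery(b, v$classification), 1)
})

test_that("full photo dropout turns every reconstruction mark Category 2", {
  ph <- generatePhantom(seed = 23, volumes = FALSE)
  cfg <- phantomConfig(photoDropout = 1, photoExtraRate = 0,
                       arteryCount = 0, occlusionCount = 0, jitterSD = 0,
                       misalignment = Similarity2D())
  b <- generatePhoto(ph, config = cfg, seed = 24)
  v <- runValidation(b, tol = 3)
  expect_true(all(v$classification$category == 2))
  expect_equal(nrow(v$classification), nrow(junctions(ph@tree)))
})

test_that("photo generation is reproducible and truth is consistent", {
  ph <- generatePhantom(seed = 25, volumes = FALSE)
  cfg <- phantomConfig()
  a <- generatePhoto(ph, config = cfg, seed = 26)
  b <- generatePhoto(ph, config = cfg, seed = 26)
  expect_identical(a$truth, b$truth)
  expect_identical(a$photoMarks@sections, b$photoMarks@sections)
  # every reconstruction mark has exactly one truth row
  expect_equal(sum(a$truth$kind == "recon"),
               length(sections(a$reconMarks)))
  # the misaligned photo is recovered by the landmark fit
  v <- runValidation(a, tol = 2 * cfg@jitterSD)
  expect_equal(v$fit@scale * cfg@misalignment@scale, 1, tolerance = 0.05)
  expect_equal(v$fit@rotation + cfg@misalignment@rotation, 0,
               tolerance = 2)
})

test_that("phantom artifacts write to standard on-disk formats", {
  cfg <- smallPhantomConfig()
  ph <- generatePhantom(cfg, seed = 31, volumes = TRUE)
  dir <- withr::local_tempdir()
  writePhantom(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("structural.nii.gz", "angiographic.nii.gz", "cortex_mask.nii.gz",
      "tree.json", "sinus.json", "truth.json")))))
  vol <- readVolume(file.path(dir, "structural.nii.gz"))
  expect_identical(voxelValues(vol), voxelValues(ph@structural))
  tree <- readVeinTree(file.path(dir, "tree.json"))
  expect_equal(nrow(junctions(tree)), nrow(junctions(ph@tree)))
})

test_that("phantom configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("photoDropout: 0.3", "jitterSD: 0.75", "fixedCounts: true"),
             path)
  cfg <- readPhantomConfig(path)
  expect_equal(cfg@photoDropout, 0.3)
  expect_equal(cfg@jitterSD, 0.75)
  expect_true(cfg@fixedCounts)
  writeLines("noSuchKey: 1", path)
  expect_error(readPhantomConfig(path), "unknown config keys")
})

test_that("invalid configurations are rejected", {
  expect_error(phantomConfig(photoDropout = 1.5), "0, 1")
  expect_error(phantomConfig(radiusRange = c(2, 1)), "increasing")
  expect_error(phantomConfig(angleMeans = c("anterior frontal" = 200,
    "medial frontal" = 85.2, "posterior frontal" = 69.5,
    "anterior parietal" = 61.1, "posterior parietal" = 47,
    "occipital" = 39.3)), "range")
})
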