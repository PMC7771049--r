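test_that("standard view directions follow the documented convention", {
  expect_equal(standardView(1)@direction, c(0, 0, -1))
  s40 <- sin(pi * 40 / 180); c40 <- cos(pi * 40 / 180)
  expect_equal(standardView(2)@direction, c(0, s40, -c40), tolerance = 1e-12)
  expect_equal(standardView(4)@direction,
               c(-cos(pi / 6), 0, -sin(pi / 6)), tolerance = 1e-12)
  expect_error(standardView(7), "1..6")
})

test_that("all views are unit frames and 2/3, 5/6 are y-mirror pairs", {
  for (id in 1:6) {
    v <- standardView(id)
    expect_equal(sum(v@direction^2), 1, tolerance = 1e-12)
    expect_equal(sum(v@up^2), 1, tolerance = 1e-12)
    expect_equal(sum(v@direction * v@up), 0, tolerance = 1e-12)
  }
  flipY <- function(v) v * c(1, -1, 1)
  expect_equal(standardView(3)@direction, flipY(standardView(2)@direction))
  expect_equal(standardView(6)@direction, flipY(standardView(5)@direction))
})

test_that("MIP takes the maximum along each viewing ray", {
  arr <- array(0, c(4, 4, 4))
  arr[2, 3, 1] <- 3
  arr[2, 3, 4] <- 7  # same (x, y) ray viewed cranially
  vol <- Volume3D(arr)
  img <- mip(vol, standardView(1), pixelSize = 1)
  expect_equal(sum(img@pixels != 0), 1)
  expect_equal(max(img@pixels), 7)
})

test_that("a single nonzero voxel projects to a single nonzero pixel", {
  arr <- array(0, c(5, 5, 5)); arr[2, 4, 3] <- 11
  img <- mip(Volume3D(arr), standardView(1), pixelSize = 1)
  expect_equal(sum(img@pixels != 0), 1)
  expect_equal(img@pixels[2, 4], 11)
})

test_that("a uniform volume projects to a uniform image", {
  img <- mip(Volume3D(array(5, c(4, 4, 4))), standardView(1), pixelSize = 1)
  expect_true(all(img@pixels == 5))
})

test_that("polyline projection preserves in-plane geometry", {
  v <- standardView(1)
  expect_equal(drop(projectPoints(c(0, 0, 0), v)), c(0, 0))
  # segment parallel to the view direction collapses to a point
  seg <- rbind(c(1, 2, 0), c(1, 2, -5))
  uv <- projectPoints(seg, v)
  expect_equal(uv[1, ], uv[2, ])
  # unit segment in the view plane keeps length 1
  seg <- rbind(c(0, 0, 0), c(1, 0, 0))
  uv <- projectPoints(seg, v)
  expect_equal(sqrt(sum((uv[2, ] - uv[1, ])^2)), 1, tolerance = 1e-9)
})

test_that("similarity fit recovers constructed transforms exactly", {
  src <- rbind(c(0, 0), c(10, 0), c(10, 5), c(2, 8))
  expect_s4_class(fitSimilarity(src, src), "Similarity2D")
  idf <- fitSimilarity(src, src)
  expect_equal(idf@scale, 1, tolerance = 1e-12)
  expect_equal(idf@rotation, 0, tolerance = 1e-12)
  expect_equal(idf@translation, c(0, 0), tolerance = 1e-12)

  truth <- Similarity2D(scale = 2, rotation = 30, translation = c(4, -7))
  dst <- applySimilarity(truth, src)
  fit <- fitSimilarity(src, dst)
  expect_equal(fit@scale, 2, tolerance = 1e-6)
  expect_equal(fit@rotation, 30, tolerance = 1e-6)
  expect_equal(fit@translation, c(4, -7), tolerance = 1e-6)
  # zero residual on an exact similarity image
  expect_lt(max(abs(applySimilarity(fit, src) - dst)), 1e-9)
})

test_that("similarity fit rejects degenerate landmark sets", {
  expect_error(fitSimilarity(rbind(c(0, 0)), rbind(c(1, 1))), "2 matched")
  same <- rbind(c(3, 3), c(3, 3))
  expect_error(fitSimilarity(same, rbind(c(0, 0), c(1, 1))), "coincident")
})

test_that("similarity inversion composes to the identity", {
  sim <- Similarity2D(scale = 1.4, rotation = -23, translation = c(3, 9))
  pts <- withr::with_seed(3, matrix(stats::rnorm(20, 0, 10), 10, 2))
  back <- applySimilarity(invertSimilarity(sim), applySimilarity(sim, pts))
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("projection images serialize to PNG with a JSON sidecar", {
  arr <- array(0, c(6, 6, 6)); arr[2:4, 3, 2:5] <- 9
  img <- mip(Volume3D(arr), standardView(1), pixelSize = 1)
  png <- withr::local_tempfile(fileext = ".png")
  writeProjectionImage(img, png)
  expect_true(file.exists(png))
  side <- jsonlite::read_json(sub("\\.png$", ".json", png),
                              simplifyVector = TRUE)
  expect_equal(side$pixel_size_mm, 1)
  expect_equal(side$view, 1)
})
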