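line2 <- function(x0, y0, x1, y1) rbind(c(x0, y0), c(x1, y1))

# three well-separated vertical vein traces
threeVeins <- function() {
  list(line2(0, 0, 0, 20), line2(15, 0, 15, 20), line2(30, 0, 30, 20))
}

test_that("identical vein sets are all Category 0", {
  recon <- VeinMarkSet("reconstruction", threeVeins())
  photo <- VeinMarkSet("photo", threeVeins())
  cl <- classifySections(recon, photo, tol = 3)
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$category == 0))
  # one-to-one: every section appears exactly once
  expect_equal(sort(cl$reconIndex), 1:3)
  expect_equal(sort(cl$photoIndex), 1:3)
})

test_that("photo-only veins are Category 1", {
  recon <- VeinMarkSet("reconstruction", list())
  photo <- VeinMarkSet("photo", threeVeins())
  cl <- classifySections(recon, photo, tol = 3)
  expect_equal(cl$category, rep(1, 3))
})

test_that("a reconstruction trace over a photo artery is Category 3", {
  recon <- VeinMarkSet("reconstruction", list(line2(0, 0, 0, 20)))
  photo <- VeinMarkSet("photo", list(line2(0.2, 0, 0.2, 20)),
                       kind = "artery")
  cl <- classifySections(recon, photo, tol = 3)
  expect_equal(cl$category, 3)
})

test_that("occluded reconstruction sections are Category 4", {
  recon <- VeinMarkSet("reconstruction",
                       list(line2(0, 0, 0, 20), line2(15, 0, 15, 20)))
  occl <- list(rbind(c(-2, -2), c(2, -2), c(2, 22), c(-2, 22)))
  photo <- VeinMarkSet("photo", list(line2(15, 0, 15, 20)),
                       occlusions = occl)
  cl <- classifySections(recon, photo, tol = 3)
  expect_equal(sort(cl$category), c(0, 4))
  expect_equal(cl$category[cl$reconIndex == 1 & cl$source == "recon"], 4)
})

test_that("an unmatched section with under half its arc occluded is Category 2", {
  recon <- VeinMarkSet("reconstruction", list(line2(0, 0, 0, 20)))
  occl <- list(rbind(c(-2, -2), c(2, -2), c(2, 5), c(-2, 5)))  # ~25% of arc
  photo <- VeinMarkSet("photo", list(line2(40, 0, 40, 20)),
                       occlusions = occl)
  cl <- classifySections(recon, photo, tol = 3)
  expect_equal(cl$category[cl$source == "recon"], 2)
})

test_that("greedy matching pairs nearest sections first, one-to-one", {
  # recon 1 is close to photo 1 and 2; the closer pair must win
  recon <- VeinMarkSet("reconstruction",
                       list(line2(0, 0, 0, 20), line2(2, 0, 2, 20)))
  photo <- VeinMarkSet("photo",
                       list(line2(0.5, 0, 0.5, 20), line2(2.1, 0, 2.1, 20)))
  cl <- classifySections(recon, photo, tol = 3)
  pairs <- cl[cl$source == "pair", ]
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$photoIndex[pairs$reconIndex == 1], 1)
  expect_equal(pairs$photoIndex[pairs$reconIndex == 2], 2)
})

test_that("matched counts agree from both sides of the comparison", {
  withr::with_seed(10, {
    for (rep in 1:5) {
      base <- lapply(1:6, function(k)
        line2(10 * k, stats::runif(1, 0, 4), 10 * k, 20))
      keepP <- stats::runif(6) < 0.7
      recon <- VeinMarkSet("reconstruction", base)
      photo <- VeinMarkSet("photo", base[keepP])
      cl <- classifySections(recon, photo, tol = 2)
      n0 <- sum(cl$category == 0)
      # photo-side count of matched sections equals recon-side count
      expect_equal(n0, sum(!is.na(cl$photoIndex) & cl$category == 0))
      expect_equal(n0 + sum(cl$category == 1), sum(keepP))
      expect_equal(sum(cl$category %in% c(0, 2, 3, 4)), 6)
    }
  })
})

test_that("category summaries partition the sections and round to one decimal", {
  s <- summarizeCategories(c(rep(0, 5)))
  expect_equal(unname(categoryPercentages(s)), c(100, 0, 0, 0, 0))
  cc <- categoryCounts(summarizeCategories(c(0, 0, 1, 2, 3, 4)))
  expect_equal(unname(cc[["total"]]), 6)
  expect_equal(unname(cc[["photo_visible"]]), 3)
  expect_equal(unname(cc[["recon_visible"]]), 5)
  expect_error(summarizeCategories(integer()), "no categorized")
  expect_error(summarizeCategories(c(0, 7)), "0..4")
})

test_that("mean symmetric distance is zero on coincident traces and symmetric", {
  a <- line2(0, 0, 10, 10)
  b <- rbind(c(0, 0), c(5, 5), c(10, 10))
  expect_equal(meanSymmetricDistance(a, b), 0, tolerance = 1e-12)
  c1 <- line2(0, 3, 10, 3)
  c2 <- line2(0, 0, 10, 0)
  expect_equal(meanSymmetricDistance(c1, c2), 3, tolerance = 1e-9)
  expect_equal(meanSymmetricDistance(c1, c2), meanSymmetricDistance(c2, c1))
})

test_that("vein mark sets round-trip through JSON", {
  marks <- VeinMarkSet("photo",
                       list(line2(0, 0, 0, 20), line2(5.5, 1, 9, 20)),
                       kind = c("vein", "artery"),
                       occlusions = list(rbind(c(0, 0), c(1, 0), c(1, 1))))
  path <- withr::local_tempfile(fileext = ".json")
  writeVeinMarkSet(marks, path)
  back <- readVeinMarkSet(path)
  expect_equal(back@source, "photo")
  expect_equal(back@kind, c("vein", "artery"))
  expect_equal(back@sections[[2]], marks@sections[[2]])
  expect_equal(back@occlusions[[1]], marks@occlusions[[1]])
})

test_that("artery marks are rejected in reconstruction sets", {
  expect_error(VeinMarkSet("reconstruction", list(line2(0, 0, 1, 1)),
                           kind = "artery"), "photo")
  expect_error(classifySections(VeinMarkSet("reconstruction", threeVeins()),
                                VeinMarkSet("photo", threeVeins()),
                                tol = 0), "positive")
})
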