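test_that("identical trial and gold give zero error on any mask", {
  mask <- shellMask(c(9, 9, 9), c(2, 2, 2), 7, 3)
  p <- RigidParams(1, -2, 3, 4, 5, -6)
  expect_equal(mcSpatialError(p, p, mask, 100, seed = 1), 0)
})

test_that("a pure-translation difference gives exactly the translation norm", {
  mask <- shellMask(c(9, 9, 9), c(2, 2, 2), 7, 3)
  trial <- RigidParams(tx = 0.6, tz = 0.8)
  gold <- RigidParams()
  # 3-4-5 triangle: ||(0.6, 0, 0.8)|| = 1 exactly, for any mask and any n
  expect_equal(mcSpatialError(trial, gold, mask, 17, seed = 2), 1)
  expect_equal(mcSpatialError(trial, gold, mask, 5000, seed = 3), 1)
  expect_equal(exhaustiveSpatialError(trial, gold, mask), 1)
})

test_that("Monte-Carlo estimate matches the exhaustive oracle for a rotation", {
  # 9x9x9 shell, 1 degree rotation about z: compare against the mean over
  # ALL mask voxel centres, within 3 standard errors of the MC estimate.
  mask <- shellMask(c(9, 9, 9), c(2, 2, 2), 7, 3)
  trial <- RigidParams(rz = 1)
  gold <- RigidParams()
  pts <- maskVoxelCenters(mask)
  tf <- paramsToTransform(trial)
  d <- sqrt(rowSums((applyTransform(tf, pts) - pts)^2))
  oracle <- mean(d)
  n <- 5000
  se <- stats::sd(d) / sqrt(n)
  mc <- mcSpatialError(trial, gold, mask, n, seed = 11)
  expect_lt(abs(mc - oracle), 3 * se)
  expect_equal(exhaustiveSpatialError(trial, gold, mask), oracle)
})

test_that("the error is symmetric in trial and gold", {
  mask <- shellMask(c(11, 11, 11), c(1.5, 1.5, 1.5), 6, 3)
  a <- RigidParams(0.3, -0.2, 0.1, 0.5, -0.4, 0.2)
  b <- RigidParams(-0.1, 0.2, 0.3, -0.2, 0.1, -0.3)
  expect_equal(mcSpatialError(a, b, mask, 2000, seed = 7),
               mcSpatialError(b, a, mask, 2000, seed = 7))
})

test_that("convergence spread is zero for translations and shrinks with n", {
  mask <- shellMask(c(11, 11, 11), c(1.5, 1.5, 1.5), 6, 3)
  gold <- RigidParams()
  expect_equal(mcConvergence(RigidParams(tx = 0.5), gold, mask,
                             nPoints = 200, nRepeats = 5, seed = 1), 0)
  rot <- RigidParams(rx = 2, rz = 3)
  spread50 <- mcConvergence(rot, gold, mask, nPoints = 50, nRepeats = 20,
                            seed = 21)
  spread5000 <- mcConvergence(rot, gold, mask, nPoints = 5000, nRepeats = 20,
                              seed = 21)
  expect_gt(spread50, spread5000)
})

test_that("observer variability averages unit means into a grand mean", {
  intra <- observerVariability(
    list(ErrorReport("p1", 0.90), ErrorReport("p2", 1.20),
         ErrorReport("p3", 0.58)), kind = "intraobserver")
  expect_equal(round(grandMean(intra), 2), 0.89)

  inter <- observerVariability(
    list(ErrorReport("u1", 0.71), ErrorReport("u2", 1.32),
         ErrorReport("u3", 0.61), ErrorReport("u4", 0.57),
         ErrorReport("u5", 0.87)), kind = "interobserver")
  expect_equal(round(grandMean(inter), 2), 0.82)

  single <- observerVariability(list(ErrorReport("only", c(0.4, 0.6))),
                                kind = "intraobserver")
  expect_equal(grandMean(single), 0.5)
})

test_that("grand means are invariant to unit ordering", {
  reports <- list(ErrorReport("a", c(0.9, 1.1)), ErrorReport("b", 0.7),
                  ErrorReport("c", c(0.2, 0.4, 0.6)))
  expect_equal(grandMean(observerVariability(reports)),
               grandMean(observerVariability(rev(reports))))
})

test_that("per-unit trial errors use the set's own geometric centre", {
  mask <- shellMask(c(11, 11, 11), c(1.5, 1.5, 1.5), 6, 3)
  ts <- generateRegistrationTrials(RigidParams(), sigmaT = 0.5, sigmaR = 0.3,
                                   n = 10, seed = 31, label = "p1")
  rep1 <- trialSetErrors(ts, mask, nPoints = 2000, seed = 5)
  expect_length(rep1@perTrial, 10)
  expect_true(all(rep1@perTrial >= 0))
  expect_gt(unitMean(rep1), 0)
})

test_that("error reports round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeErrorReport(ErrorReport("p1", c(0.8, 1.0), nPoints = 5000L,
                               seed = 9L), path)
  back <- readErrorReport(path)
  expect_equal(back@label, "p1")
  expect_equal(back@perTrial, c(0.8, 1.0))
  expect_equal(unitMean(back), 0.9)
})
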