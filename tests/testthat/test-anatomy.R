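test_that("an empty tree yields an all-zero count table", {
  sinus <- straightSinus()
  tree <- VeinTree(matrix(numeric(0), 0, 3),
                   data.frame(from = integer(), to = integer(),
                              radius = numeric(), veinId = integer()))
  cnt <- countBridgingVeins(tree, sinus)
  expect_true(all(cnt$table == 0))
  expect_equal(cnt$total, 0)
})

test_that("junctions are assigned to thirds by half-open arc intervals", {
  sinus <- straightSinus(len = 90)
  spec <- data.frame(arcFrac = c(0.1, 0.2, 0.4, 0.5, 0.9, 0.95),
                     side = c("L", "L", "R", "L", "L", "R"))
  cnt <- countBridgingVeins(handTree(sinus, spec), sinus)
  expect_equal(unname(cnt$table["L", ]), c(2, 1, 1))
  expect_equal(unname(cnt$table["R", ]), c(0, 1, 1))
  expect_equal(unname(cnt$side_totals), c(4, 2))

  # a junction exactly on a boundary goes to the posterior interval
  spec2 <- data.frame(arcFrac = 1 / 3, side = "L")
  cnt2 <- countBridgingVeins(handTree(sinus, spec2), sinus)
  expect_equal(unname(cnt2$table["L", ]), c(0, 1, 0))
})

test_that("count tables conserve totals on generated phantoms", {
  for (s in 1:5) {
    ph <- generatePhantom(seed = s, volumes = FALSE)
    cnt <- countBridgingVeins(ph@tree, ph@sinus)
    expect_equal(unname(cnt$side_totals), unname(rowSums(cnt$table)))
    expect_equal(cnt$total, nrow(junctions(ph@tree)))
    expect_identical(cnt$table, ph@truth$counts)
  }
})

test_that("confluence angles follow the posterior-tangent convention", {
  sinus <- straightSinus()          # posterior tangent is (0, -1, 0)
  tangent <- c(0, -1, 0)
  view <- standardView(1)
  expect_equal(confluenceAngle(c(1, 0, 0), tangent, view), 90)
  expect_equal(confluenceAngle(c(0, -1, 0), tangent, view), 0)
  expect_equal(confluenceAngle(c(1, -1, 0) / sqrt(2), tangent, view), 45)
  expect_equal(confluenceAngle(c(0, 1, 0), tangent, view), 180)
  expect_error(confluenceAngle(c(0, 0, 1), tangent, view), "point")
})

test_that("confluence angles are invariant to scaling and in-plane rotation", {
  vein <- c(0.3, -0.8, 0)
  tangent <- c(0, -1, 0)
  view <- standardView(1)
  a <- confluenceAngle(vein, tangent, view)
  expect_equal(confluenceAngle(10 * vein, tangent, view), a)
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(confluenceAngle(as.vector(R %*% vein),
                               as.vector(R %*% tangent), view), a,
               tolerance = 1e-9)
})

test_that("measured tree angles agree with the generator truth within 1 degree", {
  ph <- generatePhantom(seed = 8, volumes = FALSE)
  ang <- measureConfluenceAngles(ph@tree, ph@sinus)
  m <- merge(ang, ph@truth$angles, by = "veinId")
  expect_gt(nrow(m), 10)
  expect_lt(max(abs(m$angle_deg - m$angle)), 1)
  expect_identical(m$side.x, m$side.y)
  expect_identical(m$group.x, m$group.y)
  expect_true(all(ang$angle3d_deg >= 0 & ang$angle3d_deg <= 180))
})

test_that("group statistics compute mean and mean absolute deviation", {
  rec <- data.frame(group = "anterior frontal",
                    angle_deg = c(100, 110, 105))
  gs <- suppressWarnings(groupAngleStats(rec))
  expect_equal(gs$mean_deg, 105)
  expect_equal(gs$mad_deg, 10 / 3, tolerance = 1e-12)

  recEq <- data.frame(group = "occipital", angle_deg = rep(40, 4))
  expect_equal(suppressWarnings(groupAngleStats(recEq))$mad_deg, 0)
})

test_that("per-unit selection keeps at most two largest-caliber veins per group", {
  rec <- data.frame(phantom = 1, group = "occipital",
                    angle_deg = c(10, 20, 30, 40),
                    caliber = c(1, 4, 2, 3))
  gs <- suppressWarnings(groupAngleStats(rec, perUnitLimit = 2))
  expect_equal(gs$n, 2)
  expect_equal(gs$mean_deg, 30)  # calibers 4 and 3 -> angles 20, 40
})

test_that("drainage classification follows the caliber-ranking rule", {
  expect_equal(classifyDrainage(caliberTree(2, 2, 2), "L")$type, "I")
  expect_equal(classifyDrainage(caliberTree(4, 1, 1), "L")$type, "II")
  expect_equal(classifyDrainage(caliberTree(1, 4, 1.2), "L")$type, "III")
  expect_equal(classifyDrainage(caliberTree(1, 1.2, 4), "L")$type, "IV")
  expect_equal(classifyDrainage(caliberTree(2, 2, 0.2), "L")$type, "V")
  na <- classifyDrainage(caliberTree(NA, 2, 2), "L")
  expect_false(na$assessable)
  expect_true(is.na(na$type))
})

test_that("drainage frequencies tabulate assessable profiles", {
  profiles <- rbind(classifyDrainage(caliberTree(2, 2, 2), "L"),
                    classifyDrainage(caliberTree(4, 1, 1, "R"), "R"),
                    classifyDrainage(caliberTree(NA, 1, 1), "L"))
  freq <- drainageFrequencies(profiles)
  expect_equal(freq$count[freq$type == "I"], 1)
  expect_equal(freq$count[freq$type == "II"], 1)
  expect_equal(attr(freq, "unassessable"), 1)
})

test_that("vein trees and sinus models round-trip through JSON", {
  ph <- generatePhantom(seed = 12, volumes = FALSE)
  tp <- withr::local_tempfile(fileext = ".json")
  sp <- withr::local_tempfile(fileext = ".json")
  writeVeinTree(ph@tree, tp)
  writeSinusModel(ph@sinus, sp)
  tree <- readVeinTree(tp)
  sinus <- readSinusModel(sp)
  expect_equal(tree@nodes, ph@tree@nodes, tolerance = 1e-12)
  expect_equal(tree@junctions$arcPos, junctions(ph@tree)$arcPos,
               tolerance = 1e-12)
  expect_equal(arcLength(sinus), arcLength(ph@sinus), tolerance = 1e-9)
  cntA <- countBridgingVeins(tree, sinus)
  cntB <- countBridgingVeins(ph@tree, ph@sinus)
  expect_identical(cntA$table, cntB$table)
})

test_that("junction arc positions outside the sinus are an error", {
  sinus <- straightSinus(len = 90)
  tree <- handTree(sinus, data.frame(arcFrac = 0.5, side = "L"))
  tree@junctions$arcPos <- 120
  expect_error(countBridgingVeins(tree, sinus), "out of range")
})
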