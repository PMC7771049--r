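# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A small deterministic volume with reproducible pseudo-random values.
smallVolume <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), seed = 1,
                        modality = "structural") {
  vals <- withr::with_seed(seed,
    array(stats::rnorm(prod(shape), 50, 10), dim = shape))
  Volume3D(vals, spacing = spacing, origin = origin, modality = modality)
}

# Straight midline sinus along -y (anterior at +y), length `len` mm.
straightSinus <- function(len = 90, z = 0, nPoints = 31) {
  SinusModel(cbind(0, seq(len / 2, -len / 2, length.out = nPoints), z))
}

# Tree with one single-segment vein per junction spec row. `junctionSpec`
# is a data.frame with columns arcFrac, side, and optionally group/caliber.
# Each vein runs 10 mm laterally (x < 0 left, x > 0 right) from the sinus.
handTree <- function(sinus, junctionSpec) {
  L <- arcLength(sinus)
  nodes <- NULL; edges <- NULL; jrows <- NULL
  for (k in seq_len(nrow(junctionSpec))) {
    a <- junctionSpec$arcFrac[k] * L
    p0 <- sinusPointAt(sinus, a)
    sgn <- if (junctionSpec$side[k] == "R") 1 else -1
    p1 <- p0 + c(10 * sgn, 0, 0)
    base <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <- rbind(nodes, p0, p1)
    edges <- rbind(edges, data.frame(from = base + 1L, to = base + 2L,
                                     radius = 1, veinId = k))
    jrows <- rbind(jrows, data.frame(
      node = base + 1L, arcPos = a, side = junctionSpec$side[k],
      group = if ("group" %in% names(junctionSpec)) junctionSpec$group[k]
              else angleGroups[1],
      veinId = k,
      caliber = if ("caliber" %in% names(junctionSpec))
                  junctionSpec$caliber[k] else 2))
  }
  rownames(nodes) <- NULL
  VeinTree(nodes, edges, jrows,
           calibers = data.frame(hemisphere = c("L", "R"), trolard = 2,
                                 labbe = 2, sylvian = 2))
}

# Caliber table -> minimal VeinTree for drainage classification.
caliberTree <- function(trolard, labbe, sylvian, hemisphere = "L") {
  VeinTree(matrix(0, 1, 3),
           data.frame(from = 1L, to = 1L, radius = 1, veinId = 1L),
           junctions = data.frame(),
           calibers = data.frame(hemisphere = hemisphere, trolard = trolard,
                                 labbe = labbe, sylvian = sylvian))
}

# A compact phantom configuration for volume-rasterizing tests.
smallPhantomConfig <- function(...) {
  phantomConfig(gridShape = c(48L, 48L, 48L), spacing = c(3, 3, 3),
                headRadii = c(45, 60, 45), ...)
}

expect_equalParams <- function(p, q, tol = 1e-12) {
  expect_equal(translation(p), translation(q), tolerance = tol)
  expect_equal(rotationAngles(p), rotationAngles(q), tolerance = tol)
}
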