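# Synthetic phantom generator: head + cortex-shell volumes, SSS model,
# bridging-vein trees with controlled angle/count/type distributions, a
# TOF-like angiography volume, registration trial sets, and simulated
# annotated photographs with ground-truth categories.

#' Phantom generator configuration
#'
#' Defaults encode the emulated study conditions: the six confluence-angle
#' groups with means/MADs (degrees) and anatomical truncation ranges,
#' mean bridging-vein counts per sinus third and side, drainage-type
#' frequencies over a cohort of 19 (9:3:3:3:1), a 128^3 grid at 1.5 mm
#' isotropic, vein radii 1-3 mm, and the photograph confounder rates.
#'
#' @param gridShape,spacing Volume grid (voxels, mm).
#' @param headRadii Ellipsoid semi-axes (x, y, z) in mm.
#' @param shellThickness Cortical shell thickness in mm.
#' @param angleMeans,angleMADs Named per-group degrees.
#' @param angleRanges 6 x 2 truncation bounds in degrees.
#' @param countMeans 2 x 3 matrix (L/R x frontal/middle/occipital).
#' @param fixedCounts Use `round(countMeans)` instead of Poisson draws.
#' @param drainageFreq Named integer frequencies for types I-V.
#' @param radiusRange Vein radius range in mm.
#' @param vesselIntensity,noiseSD Angiographic tube intensity / noise SD.
#' @param photoDropout,photoExtraRate,arteryCount,occlusionCount,jitterSD
#'   Photograph confounder parameters.
#' @param misalignment [Similarity2D-class] mapping the aligned frame to
#'   the raw photo frame.
#' @return A validated [PhantomConfig-class].
#' @export
phantomConfig <- function(
    gridShape = c(128L, 128L, 128L),
    spacing = c(1.5, 1.5, 1.5),
    headRadii = c(65, 80, 65),
    shellThickness = 4,
    angleMeans = c("anterior frontal" = 103.5, "medial frontal" = 85.2,
                   "posterior frontal" = 69.5, "anterior parietal" = 61.1,
                   "posterior parietal" = 47.0, "occipital" = 39.3),
    angleMADs = c("anterior frontal" = 14.5, "medial frontal" = 10.3,
                  "posterior frontal" = 15.3, "anterior parietal" = 11.9,
                  "posterior parietal" = 11.2, "occipital" = 7.9),
    angleRanges = matrix(c(55, 155, 20, 160, 15, 105, 10, 95, 0, 55, 0, 45),
                         ncol = 2, byrow = TRUE,
                         dimnames = list(angleGroups, c("lo", "hi"))),
    countMeans = matrix(c(4.3, 4.4, 2.3, 4.1, 4.5, 2.0), nrow = 2,
                        byrow = TRUE,
                        dimnames = list(c("L", "R"),
                                        c("frontal", "middle", "occipital"))),
    fixedCounts = FALSE,
    drainageFreq = c(I = 9L, II = 3L, III = 3L, IV = 3L, V = 1L),
    radiusRange = c(1, 3),
    vesselIntensity = 200,
    noiseSD = 5,
    photoDropout = 0.15,
    photoExtraRate = 2,
    arteryCount = 1L,
    occlusionCount = 1L,
    jitterSD = 0.5,
    misalignment = Similarity2D(scale = 1.1, rotation = 8,
                                translation = c(5, -3))) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), headRadii = as.numeric(headRadii),
      shellThickness = shellThickness, angleMeans = angleMeans,
      angleMADs = angleMADs, angleRanges = angleRanges,
      countMeans = countMeans, fixedCounts = fixedCounts,
      drainageFreq = structure(as.integer(drainageFreq),
                               names = names(drainageFreq)),
      radiusRange = radiusRange,
      vesselIntensity = vesselIntensity, noiseSD = noiseSD,
      photoDropout = photoDropout, photoExtraRate = photoExtraRate,
      arteryCount = as.integer(arteryCount),
      occlusionCount = as.integer(occlusionCount), jitterSD = jitterSD,
      misalignment = misalignment)
}

#' Read a phantom configuration from YAML or JSON
#'
#' Recognized keys match the arguments of [phantomConfig()]; unknown keys
#' raise an error. Omitted keys keep their defaults.
#'
#' @param path YAML or JSON file.
#' @return A [PhantomConfig-class].
#' @export
readPhantomConfig <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(phantomConfig))
  bad <- setdiff(names(obj), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in c("angleMeans", "angleMADs")) {
    if (!is.null(obj[[k]])) obj[[k]] <- unlist(obj[[k]])
  }
  if (!is.null(obj$angleRanges)) {
    obj$angleRanges <- matrix(unlist(obj$angleRanges), ncol = 2, byrow = TRUE,
                              dimnames = list(angleGroups, c("lo", "hi")))
  }
  if (!is.null(obj$countMeans)) {
    obj$countMeans <- matrix(unlist(obj$countMeans), nrow = 2, byrow = TRUE,
                             dimnames = list(c("L", "R"),
                                             c("frontal", "middle",
                                               "occipital")))
  }
  if (!is.null(obj$misalignment)) {
    m <- obj$misalignment
    obj$misalignment <- Similarity2D(m$scale, m$rotation,
                                     unlist(m$translation))
  }
  do.call(phantomConfig, obj)
}

# Superior-sagittal-sinus centerline: a midline sagittal arc just below
# the head surface, anterior to posterior.
makeSinus <- function(config, nPoints = 81) {
  b <- config@headRadii[2]
  cz <- config@headRadii[3]
  y <- seq(0.8 * b, -0.8 * b, length.out = nPoints)
  z <- 0.93 * cz * sqrt(pmax(0, 1 - (y / (0.9 * b))^2))
  SinusModel(cbind(x = rep(0, nPoints), y = y, z = z))
}

sampleDrainageCalibers <- function(type) {
  base <- stats::runif(1, 1.8, 2.2)
  cal <- switch(type,
    I = base * stats::runif(3, 0.9, 1.1),
    II = c(3.5, 1.5, 1.8) * stats::runif(3, 0.95, 1.05),
    III = c(1.5, 3.5, 1.8) * stats::runif(3, 0.95, 1.05),
    IV = c(1.8, 1.5, 3.5) * stats::runif(3, 0.95, 1.05),
    V = {
      absent <- sample.int(3, 1)
      v <- base * stats::runif(3, 0.95, 1.05)
      v[absent] <- 0.2
      v
    })
  names(cal) <- c("trolard", "labbe", "sylvian")
  cal
}

#' Generate a synthetic phantom
#'
#' Builds, deterministically for a given seed, a head phantom: midline SSS
#' arc; per (side, third) bridging-vein counts drawn Poisson around the
#' configured means (or fixed); per-vein junction groups by arc position
#' with confluence angles drawn from the group's truncated normal
#' (sigma = MAD * sqrt(pi/2)); a vein tree whose terminal segments realize
#' the drawn angles exactly in the cranial view; anastomotic-vein calibers
#' per hemisphere drawn from the drainage-type frequencies; and, when
#' `volumes = TRUE`, a structural ellipsoid-plus-shell volume and a
#' TOF-like angiographic volume with the vessels rasterized as tubes over
#' Gaussian noise.
#'
#' @param config A [PhantomConfig-class].
#' @param seed Integer seed.
#' @param volumes Rasterize the structural/angiographic volumes and the
#'   cortex mask (set `FALSE` for fast tree-only phantoms; the volume
#'   slots then hold 1-voxel placeholders).
#' @return A [Phantom-class].
#' @export
generatePhantom <- function(config = phantomConfig(), seed,
                            volumes = TRUE) {
  withr::with_seed(seed, {
    sinus <- makeSinus(config)
    L <- arcLength(sinus)
    sigma <- config@angleMADs * sqrt(pi / 2)

    nodes <- NULL
    edges <- NULL
    jrows <- NULL
    veinId <- 0L
    thirdEdges <- c(0, L / 3, 2 * L / 3, L)
    for (si in 1:2) {
      side <- c("L", "R")[si]
      for (ti in 1:3) {
        nVeins <- if (config@fixedCounts) {
          as.integer(round(config@countMeans[si, ti]))
        } else {
          stats::rpois(1, config@countMeans[si, ti])
        }
        if (nVeins == 0) next
        arcs <- sort(stats::runif(nVeins, thirdEdges[ti], thirdEdges[ti + 1]))
        for (a in arcs) {
          veinId <- veinId + 1L
          gi <- min(6L, as.integer(floor(a / (L / 6))) + 1L)
          group <- angleGroups[gi]
          theta <- rtruncnorm(1, config@angleMeans[gi], sigma[gi],
                              config@angleRanges[gi, 1],
                              config@angleRanges[gi, 2])
          radius <- stats::runif(1, config@radiusRange[1],
                                 config@radiusRange[2])
          p0 <- sinusPointAt(sinus, a)
          tangent <- sinusTangentAt(sinus, a)
          tp2 <- normalizeVec(tangent[1:2])
          th <- deg2rad(theta) * if (side == "R") 1 else -1
          d2 <- c(tp2[1] * cos(th) - tp2[2] * sin(th),
                  tp2[1] * sin(th) + tp2[2] * cos(th))
          lat <- if (side == "R") 1 else -1
          # terminal 8 mm in the view-1 plane so the projected angle is
          # exactly the drawn angle; then descend laterally.
          p1 <- p0 + 8 * c(d2[1], d2[2], 0)
          dir2 <- normalizeVec(c(0.6 * lat + 0.4 * d2[1], 0.6 * d2[2], -0.45))
          p2 <- p1 + 12 * dir2
          dir3 <- normalizeVec(c(0.8 * lat, 0.3 * d2[2], -0.6))
          p3 <- p2 + 15 * dir3
          base <- if (is.null(nodes)) 0L else nrow(nodes)
          nodes <- rbind(nodes, p0, p1, p2, p3)
          edges <- rbind(edges,
                         data.frame(from = base + 1:3, to = base + 2:4,
                                    radius = radius, veinId = veinId))
          jrows <- rbind(jrows,
                         data.frame(node = base + 1L, arcPos = a,
                                    side = side, group = group,
                                    veinId = veinId, caliber = 2 * radius,
                                    angle = theta))
        }
      }
    }
    if (is.null(nodes)) {
      nodes <- matrix(numeric(0), 0, 3)
      edges <- data.frame(from = integer(), to = integer(),
                          radius = numeric(), veinId = integer())
      jrows <- data.frame(node = integer(), arcPos = numeric(),
                          side = character(), group = character(),
                          veinId = integer(), caliber = numeric(),
                          angle = numeric())
    }
    rownames(nodes) <- NULL

    types <- names(config@drainageFreq)
    calibers <- do.call(rbind, lapply(c("L", "R"), function(h) {
      type <- sample(types, 1, prob = config@drainageFreq)
      cal <- sampleDrainageCalibers(type)
      data.frame(hemisphere = h, trolard = cal[["trolard"]],
                 labbe = cal[["labbe"]], sylvian = cal[["sylvian"]],
                 truthType = type)
    }))

    junctions <- jrows[setdiff(names(jrows), "angle")]
    tree <- VeinTree(nodes = nodes, edges = edges, junctions = junctions,
                     calibers = calibers)

    countTable <- matrix(0L, 2, 3,
                         dimnames = list(c("L", "R"),
                                         c("frontal", "middle", "occipital")))
    if (nrow(jrows)) {
      third <- findInterval(jrows$arcPos, thirdEdges[2:3]) + 1L
      for (k in seq_len(nrow(jrows))) {
        countTable[jrows$side[k], third[k]] <-
          countTable[jrows$side[k], third[k]] + 1L
      }
    }

    truth <- list(
      seed = seed,
      angles = jrows[c("veinId", "group", "side", "caliber", "angle")],
      counts = countTable,
      drainage = calibers[c("hemisphere", "truthType")],
      threshold = config@vesselIntensity / 2,
      rasterized = volumes)

    if (volumes) {
      vols <- rasterizePhantom(config, sinus, tree)
      structural <- vols$structural
      angiographic <- vols$angiographic
      cortexMask <- vols$cortexMask
    } else {
      placeholder <- function(mod)
        Volume3D(array(0, c(1, 1, 1)), modality = mod)
      structural <- placeholder("structural")
      angiographic <- placeholder("angiographic")
      cortexMask <- BinaryMask(array(FALSE, c(1, 1, 1)))
    }

    new("Phantom", structural = structural, angiographic = angiographic,
        cortexMask = cortexMask, sinus = sinus, tree = tree, truth = truth)
  })
}

# Rasterize the head ellipsoid + cortical shell (structural) and the
# vessels as tubes (angiographic), with additive Gaussian noise.
rasterizePhantom <- function(config, sinus, tree) {
  shape <- config@gridShape
  sp <- config@spacing
  origin <- -(shape - 1) / 2 * sp
  grid <- VoxelGrid(shape, sp, origin)
  xs <- origin[1] + (seq_len(shape[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * sp[3]
  r <- config@headRadii
  e2 <- outer(outer((xs / r[1])^2, (ys / r[2])^2, `+`), (zs / r[3])^2, `+`)
  rad <- sqrt(e2)
  shellInner <- 1 - config@shellThickness / mean(r)
  inside <- rad <= 1
  shell <- inside & rad > shellInner

  structuralVals <- array(stats::rnorm(prod(shape), 0, config@noiseSD),
                          dim = shape)
  structuralVals[inside] <- structuralVals[inside] + 80
  structuralVals[shell] <- structuralVals[shell] + 40

  angioVals <- array(stats::rnorm(prod(shape), 0, config@noiseSD),
                     dim = shape)
  # tubes are painted with an effective radius of at least the voxel
  # half-diagonal so thin vessels stay connected after rasterization
  minRadius <- sqrt(sum(sp^2)) / 2
  paintTube <- function(vals, a, b, radius) {
    radius <- max(radius, minRadius)
    lo <- pmax(1, floor((pmin(a, b) - radius - origin) / sp) + 1)
    hi <- pmin(shape, ceiling((pmax(a, b) + radius - origin) / sp) + 1)
    if (any(lo > hi)) return(vals)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    px <- origin[1] + (ix - 1) * sp[1]
    py <- origin[2] + (iy - 1) * sp[2]
    pz <- origin[3] + (iz - 1) * sp[3]
    pts <- cbind(rep(px, times = length(py) * length(pz)),
                 rep(rep(py, each = length(px)), times = length(pz)),
                 rep(pz, each = length(px) * length(py)))
    d <- pointSegDist(pts, a, b)
    hit <- d <= radius
    if (any(hit)) {
      sub <- as.matrix(expand.grid(ix, iy, iz))[hit, , drop = FALSE]
      vals[sub] <- config@vesselIntensity
    }
    vals
  }
  cl <- sinus@centerline
  for (k in seq_len(nrow(cl) - 1)) {
    angioVals <- paintTube(angioVals, cl[k, ], cl[k + 1, ], 3.5)
  }
  for (v in unique(tree@edges$veinId)) {
    p <- veinPath(tree, v)
    radius <- tree@edges$radius[tree@edges$veinId == v][1]
    for (k in seq_len(nrow(p) - 1)) {
      angioVals <- paintTube(angioVals, p[k, ], p[k + 1, ], radius)
    }
  }

  list(structural = Volume3D(structuralVals, grid = grid,
                             modality = "structural"),
       angiographic = Volume3D(angioVals, grid = grid,
                               modality = "angiographic"),
       cortexMask = BinaryMask(shell, grid = grid))
}

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom (seed %s): %d bridging veins, sinus %.0f mm, volumes %s\n",
              object@truth$seed, nrow(object@tree@junctions),
              arcLength(object@sinus),
              if (isTRUE(object@truth$rasterized))
                paste(gridShape(object@structural), collapse = "x")
              else "not rasterized"))
})

#' Generate perturbed registration trials around a gold pose
#'
#' i.i.d. Gaussian perturbations of each of the six parameters, emulating
#' repeated interactive registrations scattering around the correct pose.
#'
#' @param gold The true [RigidParams-class].
#' @param sigmaT Translation SD in mm.
#' @param sigmaR Rotation SD in degrees.
#' @param n Number of trials.
#' @param seed Integer seed.
#' @param label Trial-set label.
#' @return A [TrialSet-class].
#' @export
generateRegistrationTrials <- function(gold, sigmaT, sigmaR, n, seed,
                                       label = "phantom") {
  stopifnot(sigmaT >= 0, sigmaR >= 0, n >= 1)
  withr::with_seed(seed, {
    tl <- lapply(seq_len(n), function(i) {
      t <- gold@translation + stats::rnorm(3, 0, sigmaT)
      r <- gold@rotation + stats::rnorm(3, 0, sigmaR)
      RigidParams(t[1], t[2], t[3], r[1], r[2], r[3])
    })
    TrialSet(label, tl)
  })
}

#' Write phantom artifacts to a directory
#'
#' Volumes and the cortex mask as NIfTI (when rasterized), the vein tree,
#' sinus model and ground truth as JSON.
#'
#' @param phantom A [Phantom-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(phantom@truth$rasterized)) {
    writeVolume(phantom@structural, file.path(dir, "structural.nii.gz"))
    writeVolume(phantom@angiographic, file.path(dir, "angiographic.nii.gz"))
    writeMask(phantom@cortexMask, file.path(dir, "cortex_mask.nii.gz"))
  }
  writeVeinTree(phantom@tree, file.path(dir, "tree.json"))
  writeSinusModel(phantom@sinus, file.path(dir, "sinus.json"))
  truth <- phantom@truth
  truth$counts <- list(L = unname(truth$counts["L", ]),
                       R = unname(truth$counts["R", ]),
                       thirds = colnames(truth$counts))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
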