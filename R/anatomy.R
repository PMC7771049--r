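# Bridging-vein counts per sinus third and side, confluence-angle
# measurement with per-group mean and MAD, and drainage-type
# classification on a VeinTree + SinusModel.

#' The six confluence-angle groups, anterior to posterior
#' @export
angleGroups <- c("anterior frontal", "medial frontal", "posterior frontal",
                 "anterior parietal", "posterior parietal", "occipital")

#' @describeIn SinusModel-class Total arc length in mm.
#' @param x Object.
#' @export
setMethod("arcLength", "SinusModel", function(x) {
  polylineLength(x@centerline)
})

#' @describeIn SinusModel-class Arc-length positions of the two third
#'   boundaries (L/3, 2L/3).
#' @export
setMethod("thirdBoundaries", "SinusModel", function(x) {
  L <- polylineLength(x@centerline)
  c(L / 3, 2 * L / 3)
})

setMethod("show", "SinusModel", function(object) {
  cat(sprintf("SinusModel: %d points, arc length %.1f mm\n",
              nrow(object@centerline), polylineLength(object@centerline)))
})

# Cumulative arc-length parameterization helpers.
sinusArcParam <- function(sinus) {
  seg <- diff(sinus@centerline)
  c(0, cumsum(sqrt(rowSums(seg^2))))
}

#' Point and tangent of the sinus at an arc-length position
#'
#' The tangent is oriented posteriorly (direction of increasing arc
#' length; the centerline runs anterior to posterior).
#'
#' @param sinus A [SinusModel-class].
#' @param arcPos Arc-length position in mm, within `[0, arcLength]`.
#' @return [sinusPointAt()]: 3D mm point; [sinusTangentAt()]: unit vector.
#' @export
sinusPointAt <- function(sinus, arcPos) {
  s <- sinusArcParam(sinus)
  if (arcPos < 0 || arcPos > s[length(s)]) stop("arc position out of range")
  vapply(1:3, function(j)
    stats::approx(s, sinus@centerline[, j], xout = arcPos)$y, numeric(1))
}

#' @rdname sinusPointAt
#' @export
sinusTangentAt <- function(sinus, arcPos) {
  s <- sinusArcParam(sinus)
  if (arcPos < 0 || arcPos > s[length(s)]) stop("arc position out of range")
  k <- max(1, min(findInterval(arcPos, s, rightmost.closed = TRUE),
                  nrow(sinus@centerline) - 1))
  normalizeVec(sinus@centerline[k + 1, ] - sinus@centerline[k, ])
}

#' @describeIn VeinTree-class The junction table.
#' @param x Object.
#' @export
setMethod("junctions", "VeinTree", function(x) x@junctions)

setMethod("show", "VeinTree", function(object) {
  cat(sprintf("VeinTree: %d nodes, %d edges, %d bridging junctions\n",
              nrow(object@nodes), nrow(object@edges),
              nrow(object@junctions)))
})

# Ordered polyline of one vein, walking the edge chain from its junction
# node outward.
veinPath <- function(tree, veinId) {
  ed <- tree@edges[tree@edges$veinId == veinId, , drop = FALSE]
  if (nrow(ed) == 0) stop("no edges for vein ", veinId)
  jn <- tree@junctions$node[tree@junctions$veinId == veinId]
  start <- if (length(jn)) jn[1] else ed$from[1]
  path <- start
  remaining <- ed
  current <- start
  while (nrow(remaining)) {
    hit <- which(remaining$from == current | remaining$to == current)
    if (!length(hit)) break
    e <- remaining[hit[1], ]
    current <- if (e$from == current) e$to else e$from
    path <- c(path, current)
    remaining <- remaining[-hit[1], , drop = FALSE]
  }
  tree@nodes[path, , drop = FALSE]
}

# All vein centerlines as a named list of n x 3 polylines.
veinPolylines <- function(tree) {
  ids <- unique(tree@edges$veinId)
  out <- lapply(ids, function(v) veinPath(tree, v))
  names(out) <- as.character(ids)
  out
}

# Hemisphere of a vein by the sign of its centroid x (RAS): x > 0 right,
# otherwise (including the exact midline) left.
veinSide <- function(tree, veinId) {
  p <- veinPath(tree, veinId)
  if (mean(p[, 1]) > 0) "R" else "L"
}

#' Count bridging veins per sinus third and side
#'
#' Assigns each bridging junction to a sinus third by its arc-length
#' position — half-open intervals `[0, L/3)`, `[L/3, 2L/3)`, `[2L/3, L]`
#' — and to a side by the sign of its vein's centroid x-coordinate.
#'
#' @param tree A [VeinTree-class].
#' @param sinus A [SinusModel-class].
#' @return List with `table` (2 x 3 matrix, rows L/R, columns
#'   frontal/middle/occipital), `side_totals` and `total`.
#' @export
countBridgingVeins <- function(tree, sinus) {
  L <- arcLength(sinus)
  b <- thirdBoundaries(sinus)
  tab <- matrix(0L, 2, 3,
                dimnames = list(c("L", "R"),
                                c("frontal", "middle", "occipital")))
  j <- tree@junctions
  if (nrow(j)) {
    if (any(j$arcPos < 0 | j$arcPos > L))
      stop("junction arc position out of range")
    third <- findInterval(j$arcPos, c(b[1], b[2])) + 1L
    side <- vapply(j$veinId, function(v) veinSide(tree, v), character(1))
    for (k in seq_len(nrow(j))) {
      tab[side[k], third[k]] <- tab[side[k], third[k]] + 1L
    }
  }
  list(table = tab, side_totals = rowSums(tab), total = sum(tab))
}

#' Planar confluence angle between a vein and the sinus
#'
#' Projects the vein's terminal unit direction (pointing from the junction
#' away from the sinus, along the vein) and the posteriorly oriented local
#' sinus tangent into the view plane and returns the planar angle between
#' them, in `[0, 180]` degrees. With this convention anterior (frontal)
#' veins are obtuse and occipital veins acute.
#'
#' @param veinDirection 3D direction of the vein at the junction.
#' @param sinusTangent 3D posteriorly oriented sinus tangent.
#' @param view A [StandardView-class] (views 1-3 for the readings).
#' @return Angle in degrees.
#' @export
confluenceAngle <- function(veinDirection, sinusTangent,
                            view = standardView(1)) {
  a <- drop(projectPoints(matrix(veinDirection, 1), view))
  b <- drop(projectPoints(matrix(sinusTangent, 1), view))
  na <- vecNorm(a); nb <- vecNorm(b)
  if (na < 1e-12 || nb < 1e-12)
    stop("segment projects to a point in this view")
  rad2deg(acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))))
}

#' Measure confluence angles for every bridging junction of a tree
#'
#' The terminal vein direction is estimated as the chord over the first
#' `terminalLength` mm of the vein centerline from the junction, damping
#' tracing noise. Reports both the projected angle in the requested view
#' and the true 3D angle.
#'
#' @param tree A [VeinTree-class].
#' @param sinus A [SinusModel-class].
#' @param view A [StandardView-class] (default view 1).
#' @param terminalLength Arc length (mm) over which the terminal direction
#'   is taken.
#' @return data.frame with columns `veinId`, `group`, `side`, `caliber`,
#'   `angle_deg`, `angle3d_deg`.
#' @export
measureConfluenceAngles <- function(tree, sinus, view = standardView(1),
                                    terminalLength = 5) {
  j <- tree@junctions
  rows <- lapply(seq_len(nrow(j)), function(k) {
    path <- veinPath(tree, j$veinId[k])
    rs <- resamplePolyline(path, step = terminalLength / 10)
    arc <- c(0, cumsum(sqrt(rowSums(diff(rs)^2))))
    endIdx <- max(2, findInterval(terminalLength, arc, rightmost.closed = TRUE))
    endIdx <- min(endIdx, nrow(rs))
    d <- rs[endIdx, ] - rs[1, ]
    tangent <- sinusTangentAt(sinus, j$arcPos[k])
    a2 <- confluenceAngle(d, tangent, view)
    a3 <- rad2deg(acos(pmin(1, pmax(-1,
      sum(normalizeVec(d) * tangent)))))
    data.frame(veinId = j$veinId[k], group = j$group[k],
               side = veinSide(tree, j$veinId[k]), caliber = j$caliber[k],
               angle_deg = a2, angle3d_deg = a3)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(veinId = integer(), group = character(),
                      side = character(), caliber = numeric(),
                      angle_deg = numeric(), angle3d_deg = numeric())
  out
}

#' Per-group mean and mean absolute deviation of confluence angles
#'
#' If the records carry a `phantom` (or `patient`) column, at most
#' `perUnitLimit` veins per group and unit are used, taking the
#' largest-caliber veins first — mirroring the up-to-two-veins-per-group
#' sampling rule. MAD is the mean absolute deviation from the group mean,
#' `(1/n) * sum(|x_i - mean|)`.
#'
#' @param records data.frame with columns `group`, `angle_deg`, optional
#'   `caliber` and `phantom`/`patient`.
#' @param perUnitLimit Maximum veins per group per unit (default 2).
#' @return data.frame with columns `group`, `n`, `mean_deg`, `mad_deg`;
#'   attribute `total` holds the total record count. Groups without
#'   records are dropped with a warning.
#' @export
groupAngleStats <- function(records, perUnitLimit = 2) {
  unitCol <- intersect(c("phantom", "patient"), names(records))[1]
  if (!is.na(unitCol) && "caliber" %in% names(records)) {
    keep <- unlist(lapply(
      split(seq_len(nrow(records)),
            list(records[[unitCol]], records$group), drop = TRUE),
      function(idx) idx[order(-records$caliber[idx])][
        seq_len(min(perUnitLimit, length(idx)))]))
    records <- records[sort(keep), , drop = FALSE]
  }
  present <- intersect(angleGroups, unique(records$group))
  missing <- setdiff(angleGroups, present)
  if (length(missing))
    warning("no records for group(s): ", paste(missing, collapse = ", "))
  rows <- lapply(present, function(g) {
    x <- records$angle_deg[records$group == g]
    data.frame(group = g, n = length(x), mean_deg = mean(x),
               mad_deg = mean(abs(x - mean(x))))
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$n)
  out
}

#' Classify the hemispheric venous drainage type
#'
#' Deterministic stand-in rule on the caliber ranking of the three large
#' anastomotic veins (Trolard, Labbé, superficial Sylvian). A vessel with
#' caliber below `absentBelow` mm counts as absent. Type I: all three
#' present and balanced (max/min caliber ratio below `balancedRatio`);
#' Type II/III/IV: Trolard / Labbé / Sylvian dominant; Type V: one vessel
#' absent and the remaining two co-dominant. This is an explicit
#' parameterized rule, not the published classification, whose definitions
#' are in an external reference.
#'
#' @param tree A [VeinTree-class] with a `calibers` table.
#' @param hemisphere `"L"` or `"R"`.
#' @param balancedRatio Co-dominance ratio threshold (default 1.5).
#' @param absentBelow Absence caliber threshold in mm (default 0.3).
#' @return data.frame with columns `hemisphere`, `type` (NA when not
#'   assessable), `assessable`.
#' @export
classifyDrainage <- function(tree, hemisphere, balancedRatio = 1.5,
                             absentBelow = 0.3) {
  row <- tree@calibers[tree@calibers$hemisphere == hemisphere, , drop = FALSE]
  if (nrow(row) != 1)
    stop("no caliber record for hemisphere ", hemisphere)
  cal <- c(trolard = row$trolard, labbe = row$labbe, sylvian = row$sylvian)
  if (any(is.na(cal)))
    return(data.frame(hemisphere = hemisphere, type = NA_character_,
                      assessable = FALSE))
  dominantType <- c(trolard = "II", labbe = "III", sylvian = "IV")
  present <- cal >= absentBelow
  type <- if (sum(present) <= 1) {
    dominantType[[names(which.max(cal))]]
  } else if (sum(present) == 2) {
    p <- cal[present]
    if (max(p) / min(p) < balancedRatio) "V"
    else dominantType[[names(which.max(p))]]
  } else {
    if (max(cal) / min(cal) < balancedRatio) "I"
    else dominantType[[names(which.max(cal))]]
  }
  data.frame(hemisphere = hemisphere, type = type, assessable = TRUE)
}

#' Drainage-type frequency table
#'
#' @param profiles data.frame rows from [classifyDrainage()] (possibly
#'   over many phantoms/hemispheres).
#' @return data.frame with columns `type` (I-V), `count`, plus an
#'   `unassessable` attribute.
#' @export
drainageFrequencies <- function(profiles) {
  lv <- c("I", "II", "III", "IV", "V")
  assessed <- profiles[profiles$assessable, , drop = FALSE]
  out <- data.frame(type = lv,
                    count = vapply(lv, function(t)
                      sum(assessed$type == t), integer(1)))
  attr(out, "unassessable") <- sum(!profiles$assessable)
  out
}

#' Read / write a vein tree as JSON
#'
#' @param path File path.
#' @return [readVeinTree()] returns a [VeinTree-class].
#' @export
readVeinTree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  VeinTree(nodes = matrix(obj$nodes, ncol = 3),
           edges = as.data.frame(obj$edges),
           junctions = as.data.frame(obj$junctions),
           calibers = as.data.frame(obj$calibers))
}

#' @param tree A [VeinTree-class].
#' @rdname readVeinTree
#' @export
writeVeinTree <- function(tree, path) {
  jsonlite::write_json(list(nodes = tree@nodes, edges = tree@edges,
                            junctions = tree@junctions,
                            calibers = tree@calibers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a sinus model as JSON
#'
#' @param path File path.
#' @return [readSinusModel()] returns a [SinusModel-class].
#' @export
readSinusModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  SinusModel(matrix(obj$centerline, ncol = 3))
}

#' @param sinus A [SinusModel-class].
#' @rdname readSinusModel
#' @export
writeSinusModel <- function(sinus, path) {
  jsonlite::write_json(list(centerline = sinus@centerline), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
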