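# Threshold-based merging of the structural (primary) and angiographic
# (secondary) volumes, and threshold-sensitivity metrics.

#' @describeIn CombinedVolume-class The vein label array.
#' @param x Object.
#' @export
setMethod("veinLabel", "CombinedVolume", function(x) x@veinLabel)

#' @export
setMethod("voxelValues", "CombinedVolume", function(x) x@structural)

#' @export
setMethod("gridShape", "CombinedVolume", function(x) x@grid@shape)

setMethod("show", "CombinedVolume", function(object) {
  cat(sprintf(
    "CombinedVolume: %s voxels, threshold %g, %d vein-labelled voxels\n",
    paste(object@grid@shape, collapse = "x"), object@threshold,
    sum(object@veinLabel)))
})

#' Fuse structural and angiographic volumes
#'
#' Copies the structural channel and labels every voxel whose secondary
#' (angiographic) value lies strictly above the threshold — the
#' "monochrome blue" overlay of the combined data set, stored as a
#' boolean label.
#'
#' @param primary Structural [Volume3D-class].
#' @param secondary Angiographic [Volume3D-class], already resampled to
#'   the primary grid through the registration transform.
#' @param threshold Brightness threshold on the secondary volume.
#' @return A [CombinedVolume-class].
#' @export
fuseVolumes <- function(primary, secondary, threshold) {
  if (!sameGrid(primary@grid, secondary@grid))
    stop("primary and secondary volumes must share one grid")
  stopifnot(is.finite(threshold))
  new("CombinedVolume", grid = primary@grid, structural = primary@values,
      veinLabel = secondary@values > threshold, threshold = threshold)
}

#' Write a combined volume as two NIfTI files
#'
#' @param combined A [CombinedVolume-class].
#' @param structuralPath,labelPath Output paths.
#' @export
writeCombinedVolume <- function(combined, structuralPath, labelPath) {
  writeVolume(Volume3D(combined@structural, grid = combined@grid,
                       modality = "structural"), structuralPath)
  writeMask(BinaryMask(combined@veinLabel, grid = combined@grid), labelPath)
  invisible(c(structuralPath, labelPath))
}

# 26-connected component count over a logical 3D array, via a voxel
# adjacency graph (13 forward neighbour offsets).
countComponents26 <- function(lab) {
  n <- sum(lab)
  if (n == 0) return(0L)
  dims <- dim(lab)
  lin <- which(lab)
  id <- integer(prod(dims))
  id[lin] <- seq_along(lin)
  ind <- arrayInd(lin, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[(offsets[, 3] > 0) |
                     (offsets[, 3] == 0 & offsets[, 2] > 0) |
                     (offsets[, 3] == 0 & offsets[, 2] == 0 &
                      offsets[, 1] > 0), , drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(ind, 2, offsets[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nbLin <- (nb[ok, 3] - 1) * dims[1] * dims[2] +
             (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    hit <- id[nbLin] > 0
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], id[nbLin[hit]]))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

#' Threshold sweep over an angiographic volume
#'
#' For each threshold, counts the vein-labelled voxels and the number of
#' 26-connected components of the label — the quantitative face of the
#' too-high ("discontinuous and broken") versus too-low ("background
#' noise") threshold trade-off.
#'
#' @param secondary Angiographic [Volume3D-class].
#' @param thresholds Strictly ascending numeric vector.
#' @return data.frame with columns `threshold`, `vein_voxels`,
#'   `components`.
#' @export
thresholdSweep <- function(secondary, thresholds) {
  if (length(thresholds) == 0)
    return(data.frame(threshold = numeric(), vein_voxels = integer(),
                      components = integer()))
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly ascending")
  rows <- lapply(thresholds, function(th) {
    lab <- secondary@values > th
    data.frame(threshold = th, vein_voxels = sum(lab),
               components = countComponents26(lab))
  })
  do.call(rbind, rows)
}
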