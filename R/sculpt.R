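# Volume sculpting: removal of voxels projecting into a marked 2D region,
# perpendicular to the viewing plane, and manual slice-wise segmentation.

#' SculptStep: one cut of the volume-sculpting process
#'
#' The polygon is drawn in the projection plane of `view` (mm, in the
#' view's (u, v) frame); every voxel whose orthographic projection falls
#' strictly inside it is cut away, the workstation's depth-unbounded
#' "perpendicular to the viewing plane" removal.
#'
#' @slot view A [StandardView-class] (use [customView()] for arbitrary
#'   directions).
#' @slot polygon Closed polygon as an n x 2 mm matrix, n >= 3,
#'   non-self-intersecting.
#' @export
setClass("SculptStep",
  representation(view = "StandardView", polygon = "matrix"))

setValidity("SculptStep", function(object) {
  msg <- character()
  if (!is.matrix(object@polygon) || ncol(object@polygon) != 2 ||
      nrow(object@polygon) < 3)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  else if (!polygonSimple(object@polygon))
    msg <- c(msg, "polygon must be non-self-intersecting")
  if (length(msg)) msg else TRUE
})

#' @param view,polygon See slots.
#' @rdname SculptStep-class
#' @export
SculptStep <- function(view, polygon) {
  new("SculptStep", view = view, polygon = as.matrix(polygon))
}

#' SliceMaskSet: manual slice-wise segmentation marks
#'
#' @slot axis One of `"sagittal"` (x slices), `"coronal"` (y slices),
#'   `"axial"` (z slices).
#' @slot masks Named list: 1-based slice index -> 2D logical mask matching
#'   the slice shape.
#' @slot mode `"keep"` (zero everything unmarked on marked slices) or
#'   `"remove"` (zero the marked voxels).
#' @export
setClass("SliceMaskSet",
  representation(axis = "character", masks = "list", mode = "character"))

setValidity("SliceMaskSet", function(object) {
  msg <- character()
  if (!object@axis %in% c("sagittal", "coronal", "axial"))
    msg <- c(msg, "axis must be sagittal, coronal or axial")
  if (!object@mode %in% c("keep", "remove"))
    msg <- c(msg, "mode must be keep or remove")
  if (length(object@masks) && is.null(names(object@masks)))
    msg <- c(msg, "masks must be named by slice index")
  if (length(msg)) msg else TRUE
})

#' @param axis,masks,mode See slots.
#' @rdname SliceMaskSet-class
#' @export
SliceMaskSet <- function(axis, masks, mode = c("keep", "remove")) {
  mode <- match.arg(mode)
  new("SliceMaskSet", axis = axis, masks = masks, mode = mode)
}

#' Apply one sculpting cut to a volume
#'
#' Every voxel whose orthographic projection along the view direction
#' falls strictly inside the step's polygon is set to the background value
#' 0; all other voxels — including those whose centre projects exactly
#' onto the polygon boundary — are unchanged.
#'
#' @param volume A [Volume3D-class].
#' @param step A [SculptStep-class].
#' @return The sculpted [Volume3D-class].
#' @export
sculptCut <- function(volume, step) {
  basis <- viewBasis(step@view)
  grid <- volume@grid
  ind <- arrayInd(seq_along(volume@values), dim(volume@values))
  pts <- sweep(sweep(ind - 1, 2, grid@spacing, `*`), 2, grid@origin, `+`)
  u <- pts %*% basis$u
  v <- pts %*% basis$v
  inside <- pracma::inpolygon(as.vector(u), as.vector(v),
                              step@polygon[, 1], step@polygon[, 2],
                              boundary = FALSE)
  vals <- volume@values
  vals[inside] <- 0
  Volume3D(vals, grid = grid, modality = volume@modality)
}

#' Apply a sequence of sculpting cuts
#'
#' Equivalent to removing the union of the cuts' 3D regions — the
#' "peeling an apple" iteration over rotated views.
#'
#' @param volume A [Volume3D-class].
#' @param steps List of [SculptStep-class].
#' @return The sculpted [Volume3D-class].
#' @export
sculptSequence <- function(volume, steps) {
  for (s in steps) volume <- sculptCut(volume, s)
  volume
}

#' Apply manual slice-wise segmentation marks
#'
#' In `"keep"` mode, on every marked slice all voxels outside the mark are
#' zeroed (only the stamped veins survive); in `"remove"` mode the marked
#' voxels are zeroed. Slices without marks are untouched.
#'
#' @param volume A [Volume3D-class].
#' @param maskSet A [SliceMaskSet-class].
#' @return The segmented [Volume3D-class].
#' @export
applySliceMasks <- function(volume, maskSet) {
  axisDim <- match(maskSet@axis, c("sagittal", "coronal", "axial"))
  vals <- volume@values
  nSlices <- dim(vals)[axisDim]
  sliceShape <- dim(vals)[-axisDim]
  for (nm in names(maskSet@masks)) {
    k <- as.integer(nm)
    if (is.na(k) || k < 1 || k > nSlices)
      stop("slice index ", nm, " out of bounds")
    m <- maskSet@masks[[nm]]
    if (!identical(dim(m), as.integer(sliceShape)))
      stop("mask shape for slice ", nm, " does not match the slice shape")
    sl <- switch(axisDim,
                 vals[k, , ],
                 vals[, k, ],
                 vals[, , k])
    if (maskSet@mode == "keep") sl[!m] <- 0 else sl[m] <- 0
    switch(axisDim,
           vals[k, , ] <- sl,
           vals[, k, ] <- sl,
           vals[, , k] <- sl)
  }
  Volume3D(vals, grid = volume@grid, modality = volume@modality)
}
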