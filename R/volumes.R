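# Volume and mask data model: accessors, NIfTI I/O, thresholding and
# masked random point sampling.

#' @describeIn VoxelGrid-class Voxel spacing in mm.
#' @param x Object.
#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @describeIn VoxelGrid-class World origin in mm.
#' @export
setMethod("worldOrigin", "VoxelGrid", function(x) x@origin)

#' @describeIn VoxelGrid-class Grid dimensions in voxels.
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)

#' @export
setMethod("spacing", "Volume3D", function(x) x@grid@spacing)

#' @export
setMethod("worldOrigin", "Volume3D", function(x) x@grid@origin)

#' @export
setMethod("gridShape", "Volume3D", function(x) x@grid@shape)

#' @describeIn Volume3D-class Modality tag.
#' @export
setMethod("modality", "Volume3D", function(x) x@modality)

#' @describeIn Volume3D-class The voxel value array.
#' @export
setMethod("voxelValues", "Volume3D", function(x) x@values)

#' @export
setMethod("spacing", "BinaryMask", function(x) x@grid@spacing)

#' @export
setMethod("worldOrigin", "BinaryMask", function(x) x@grid@origin)

#' @export
setMethod("gridShape", "BinaryMask", function(x) x@grid@shape)

#' @describeIn BinaryMask-class The logical inclusion array.
#' @export
setMethod("maskArray", "BinaryMask", function(x) x@included)

#' @describeIn BinaryMask-class Number of included voxels.
#' @export
setMethod("maskCount", "BinaryMask", function(x) sum(x@included))

setMethod("show", "Volume3D", function(object) {
  cat(sprintf("Volume3D [%s]: %s voxels @ %s mm, range [%g, %g]\n",
              object@modality,
              paste(object@grid@shape, collapse = "x"),
              paste(signif(object@grid@spacing, 4), collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %s voxels @ %s mm, %d included\n",
              paste(object@grid@shape, collapse = "x"),
              paste(signif(object@grid@spacing, 4), collapse = "x"),
              sum(object@included)))
})

sameGrid <- function(a, b, tol = 1e-6) {
  identical(as.integer(a@shape), as.integer(b@shape)) &&
    max(abs(a@spacing - b@spacing)) <= tol &&
    max(abs(a@origin - b@origin)) <= tol
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' The grid geometry (spacing, origin) is taken from the NIfTI transform;
#' volumes are assumed axis-aligned RAS.
#'
#' @param path Path to a `.nii`/`.nii.gz` file with 3D data.
#' @param modality Modality tag to attach.
#' @return A [Volume3D-class].
#' @export
readVolume <- function(path, modality = "structural") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L)
    stop("expected 3D NIfTI data, got ", length(dim(arr)), "D")
  xf <- RNifti::xform(img)
  Volume3D(arr, spacing = diag(xf[1:3, 1:3]), origin = xf[1:3, 4],
           modality = modality)
}

#' Write a 3D volume as NIfTI-1
#'
#' Values are stored as float64 so a round trip is bit-exact.
#'
#' @param volume A [Volume3D-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@values, datatype = "double")
  xf <- diag(4)
  diag(xf)[1:3] <- volume@grid@spacing
  xf[1:3, 4] <- volume@grid@origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a binary mask as a 0/1 NIfTI volume
#'
#' @param path File path.
#' @return [readMask()] returns a [BinaryMask-class].
#' @export
readMask <- function(path) {
  vol <- readVolume(path, modality = "pet")
  BinaryMask(vol@values != 0, grid = vol@grid)
}

#' @param mask A [BinaryMask-class].
#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  writeVolume(Volume3D(array(as.double(mask@included), dim(mask@included)),
                       grid = mask@grid, modality = "pet"),
              path)
}

#' Threshold a volume into a binary mask
#'
#' Strict inequality: a voxel is included iff its value is greater than
#' the threshold.
#'
#' @param volume A [Volume3D-class].
#' @param threshold Finite scalar.
#' @return A [BinaryMask-class] on the same grid.
#' @export
maskFromThreshold <- function(volume, threshold) {
  stopifnot(is.finite(threshold))
  BinaryMask(volume@values > threshold, grid = volume@grid)
}

#' World coordinates of all included voxel centres
#'
#' @param mask A [BinaryMask-class].
#' @return n x 3 matrix of mm points, in column-major voxel order.
#' @export
maskVoxelCenters <- function(mask) {
  ind <- which(mask@included, arr.ind = TRUE)
  out <- sweep(sweep(ind - 1, 2, mask@grid@spacing, `*`), 2,
               mask@grid@origin, `+`)
  dimnames(out) <- NULL
  out
}

#' Sample random points from a mask
#'
#' Draws `n` included voxels uniformly with replacement and returns their
#' world-coordinate centres. Deterministic given the seed.
#'
#' @param mask A non-empty [BinaryMask-class].
#' @param n Number of points (>= 1).
#' @param seed Integer seed.
#' @return n x 3 matrix of mm points.
#' @export
sampleMaskPoints <- function(mask, n, seed) {
  centers <- maskVoxelCenters(mask)
  if (nrow(centers) == 0) stop("mask is empty")
  stopifnot(n >= 1)
  idx <- withr::with_seed(seed, sample.int(nrow(centers), n, replace = TRUE))
  centers[idx, , drop = FALSE]
}

#' Spherical-shell mask
#'
#' Convenience constructor for a cortex-like spherical shell: voxels whose
#' centre distance r from `center` satisfies `radius - thickness < r <=
#' radius`.
#'
#' @param shape Grid shape (voxels).
#' @param spacing Voxel spacing (mm).
#' @param radius Outer shell radius (mm).
#' @param thickness Shell thickness (mm).
#' @param origin Grid origin; default centres the grid on the world
#'   origin.
#' @return A [BinaryMask-class].
#' @export
shellMask <- function(shape, spacing, radius, thickness,
                      origin = -(shape - 1) / 2 * spacing) {
  grid <- VoxelGrid(shape, spacing, origin)
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  BinaryMask(r2 <= radius^2 & r2 > (radius - thickness)^2, grid = grid)
}
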