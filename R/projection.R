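# Standardized views, orthographic maximum-intensity projection,
# 3D-polyline projection, and 2D similarity alignment of photograph to
# reconstruction.

#' Construct a custom orthographic view
#'
#' @param direction Viewing direction (toward the head); normalized.
#' @param up In-plane up vector; the component parallel to `direction` is
#'   removed before normalization. Default: projection of +z (superior),
#'   or +y (anterior) for near-axial directions.
#' @return A [StandardView-class] with id 0.
#' @export
customView <- function(direction, up = NULL) {
  d <- normalizeVec(direction)
  if (is.null(up)) {
    up <- if (abs(d[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  }
  u <- up - sum(up * d) * d
  new("StandardView", id = 0L, direction = d, up = normalizeVec(u))
}

#' The six standardized anatomical views
#'
#' Fixed orthographic views used for the anatomical readings (RAS;
#' "cranial" = viewing along -z): view 1 is the perpendicular cranial
#' view; views 2/3 tilt it 40 deg toward frontal (+y) / occipital (-y);
#' view 4 is the lateral view (-x) tilted 30 deg cranial; views 5/6 start
#' from the lateral view, tilt 30 deg frontal/occipital first, then
#' 30 deg cranial.
#'
#' @param id View number 1-6.
#' @return A [StandardView-class].
#' @export
standardView <- function(id) {
  if (!id %in% 1:6) stop("view id must be in 1..6")
  s30 <- sin(deg2rad(30)); c30 <- cos(deg2rad(30))
  s40 <- sin(deg2rad(40)); c40 <- cos(deg2rad(40))
  d <- switch(id,
    c(0, 0, -1),
    c(0, s40, -c40),
    c(0, -s40, -c40),
    c(-c30, 0, -s30),
    c(-c30 * c30, s30 * c30, -s30),
    c(-c30 * c30, -s30 * c30, -s30))
  v <- customView(d)
  v@id <- as.integer(id)
  v
}

setMethod("show", "StandardView", function(object) {
  cat(sprintf("StandardView %d: direction (%s), up (%s)\n", object@id,
              paste(signif(object@direction, 4), collapse = ", "),
              paste(signif(object@up, 4), collapse = ", ")))
})

# In-plane orthonormal basis: u ("right") = direction x up, v = up.
viewBasis <- function(view) {
  list(u = cross3(view@direction, view@up), v = view@up)
}

#' Project 3D points into a view plane
#'
#' @param points n x 3 mm matrix.
#' @param view A [StandardView-class].
#' @return n x 2 matrix of in-plane (u, v) mm coordinates.
#' @export
projectPoints <- function(points, view) {
  basis <- viewBasis(view)
  points <- matrix(points, ncol = 3)
  cbind(points %*% basis$u, points %*% basis$v)
}

#' Orthographic maximum-intensity projection
#'
#' Projects every voxel centre into the view plane and takes, per pixel,
#' the maximum voxel value falling on that pixel's viewing ray. Pixels hit
#' by no voxel are 0.
#'
#' @param volume A [Volume3D-class].
#' @param view A [StandardView-class].
#' @param pixelSize Pixel edge length in mm (> 0).
#' @return A [ProjectionImage-class].
#' @export
mip <- function(volume, view, pixelSize = min(spacing(volume))) {
  stopifnot(pixelSize > 0)
  grid <- volume@grid
  ind <- arrayInd(seq_along(volume@values), dim(volume@values))
  pts <- sweep(sweep(ind - 1, 2, grid@spacing, `*`), 2, grid@origin, `+`)
  uv <- projectPoints(pts, view)
  u0 <- min(uv[, 1]); v0 <- min(uv[, 2])
  i <- floor((uv[, 1] - u0) / pixelSize) + 1L
  j <- floor((uv[, 2] - v0) / pixelSize) + 1L
  ni <- max(i); nj <- max(j)
  img <- matrix(0, ni, nj)
  vals <- as.vector(volume@values)
  o <- order(vals)  # last write wins => maximum
  img[cbind(i[o], j[o])] <- vals[o]
  new("ProjectionImage", pixels = img, pixelSize = pixelSize, view = view,
      origin2d = c(u0 + pixelSize / 2, v0 + pixelSize / 2))
}

setMethod("show", "ProjectionImage", function(object) {
  cat(sprintf("ProjectionImage: %d x %d px @ %g mm (view %d)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              object@view@id))
})

#' Write a projection image as PNG with a JSON sidecar
#'
#' Pixel values are linearly rescaled to `[0, 1]`; the sidecar records the
#' pixel size, view id and in-plane origin.
#'
#' @param image A [ProjectionImage-class].
#' @param pngPath,jsonPath Output paths.
#' @export
writeProjectionImage <- function(image, pngPath,
                                 jsonPath = sub("\\.png$", ".json", pngPath)) {
  px <- image@pixels
  rng <- range(px)
  if (diff(rng) > 0) px <- (px - rng[1]) / diff(rng)
  # PNG rows run top-to-bottom; flip v so "up" is up.
  png::writePNG(t(px)[rev(seq_len(ncol(px))), , drop = FALSE], pngPath)
  jsonlite::write_json(list(pixel_size_mm = image@pixelSize,
                            view = image@view@id,
                            origin2d_mm = image@origin2d,
                            value_range = rng),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(pngPath)
}

#' Project the polylines of a vein tree
#'
#' Maps every vein centerline through the same orthographic frame as
#' [mip()], preserving connectivity.
#'
#' @param tree A [VeinTree-class], or a list of n x 3 polylines.
#' @param view A [StandardView-class].
#' @return Named list of n x 2 polylines (mm, view frame).
#' @export
projectPolylines <- function(tree, view) {
  polys <- if (is(tree, "VeinTree")) veinPolylines(tree) else tree
  lapply(polys, projectPoints, view = view)
}

#' Least-squares 2D similarity between matched landmarks
#'
#' Closed-form orthogonal-Procrustes-with-scale solution (rotation only,
#' no reflection): the returned transform, applied to `src`, minimizes the
#' summed squared distance to `dst`. Models the manual rotate-and-scale
#' alignment of photograph to reconstruction.
#'
#' @param src,dst Matched n x 2 point sets, n >= 2, not all coincident.
#' @return A [Similarity2D-class].
#' @export
fitSimilarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2 || nrow(dst) != nrow(src))
    stop("need >= 2 matched landmark pairs")
  ms <- colMeans(src); md <- colMeans(dst)
  sc <- sweep(src, 2, ms); dc <- sweep(dst, 2, md)
  denom <- sum(sc^2)
  if (denom == 0) stop("source landmarks are all coincident")
  zs <- complex(real = sc[, 1], imaginary = sc[, 2])
  zd <- complex(real = dc[, 1], imaginary = dc[, 2])
  w <- sum(Conj(zs) * zd) / denom
  scale <- Mod(w)
  if (scale == 0) stop("degenerate landmark configuration")
  theta <- Arg(w)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  trans <- md - scale * as.vector(R %*% ms)
  Similarity2D(scale = scale, rotation = rad2deg(theta), translation = trans)
}

#' Apply a 2D similarity to points or polylines
#'
#' @param sim A [Similarity2D-class].
#' @param x n x 2 matrix, or a list of such matrices.
#' @return Transformed points in the same layout.
#' @export
applySimilarity <- function(sim, x) {
  if (is.list(x) && !is.matrix(x)) return(lapply(x, applySimilarity, sim = sim))
  th <- deg2rad(sim@rotation)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sim@scale * as.matrix(x) %*% t(R), 2, sim@translation, `+`)
}

#' Invert a 2D similarity
#'
#' @param sim A [Similarity2D-class].
#' @return The inverse [Similarity2D-class].
#' @export
invertSimilarity <- function(sim) {
  th <- deg2rad(sim@rotation)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Similarity2D(scale = 1 / sim@scale, rotation = -sim@rotation,
               translation = as.vector(-t(R) %*% sim@translation) / sim@scale)
}

setMethod("show", "Similarity2D", function(object) {
  cat(sprintf("Similarity2D: scale %.4f, rotation %.3f deg, t = (%s) mm\n",
              object@scale, object@rotation,
              paste(signif(object@translation, 5), collapse = ", ")))
})
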