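# Central S4 data model. All world coordinates are RAS millimetres
# (+x right, +y anterior, +z superior); voxel indices are 0-based and a
# voxel's world point is its centre: world = origin + index * spacing.

#' VoxelGrid: geometry of a regular voxel lattice
#'
#' Holds the shape (voxels), spacing (mm) and world origin (mm, RAS) of a
#' 3D voxel grid. The world point of 0-based voxel index `i` is
#' `origin + i * spacing`, i.e. the voxel centre.
#'
#' @slot shape Integer triple, grid dimensions in voxels.
#' @slot spacing Numeric triple, voxel size in mm (all > 0).
#' @slot origin Numeric triple, world coordinate of the first voxel centre.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' @param shape,spacing,origin See slots.
#' @rdname VoxelGrid-class
#' @export
VoxelGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VoxelGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Volume3D: scalar volume on a VoxelGrid
#'
#' @slot grid A [VoxelGrid-class].
#' @slot values Numeric 3D array matching the grid shape, all finite.
#' @slot modality One of `"structural"`, `"angiographic"`, `"combined"`,
#'   `"pet"`.
#' @export
setClass("Volume3D",
  representation(grid = "VoxelGrid", values = "array", modality = "character"))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values array shape must equal grid shape")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must all be finite")
  if (!object@modality %in% c("structural", "angiographic", "combined", "pet"))
    msg <- c(msg, "unknown modality tag")
  if (length(msg)) msg else TRUE
})

#' @param values 3D numeric array.
#' @param spacing,origin Grid geometry in mm.
#' @param modality Modality tag.
#' @param grid Optionally a ready-made [VoxelGrid-class] (overrides
#'   spacing/origin).
#' @rdname Volume3D-class
#' @export
Volume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     modality = "structural", grid = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) grid <- VoxelGrid(dim(values), spacing, origin)
  new("Volume3D", grid = grid, values = values, modality = modality)
}

#' BinaryMask: inclusion mask on a VoxelGrid
#'
#' @slot grid A [VoxelGrid-class].
#' @slot included Logical 3D array matching the grid shape.
#' @export
setClass("BinaryMask",
  representation(grid = "VoxelGrid", included = "array"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!identical(dim(object@included), as.integer(object@grid@shape)))
    msg <- c(msg, "included array shape must equal grid shape")
  if (!is.logical(object@included))
    msg <- c(msg, "included must be a logical array")
  if (length(msg)) msg else TRUE
})

#' @param included Logical 3D array.
#' @param spacing,origin,grid As for [Volume3D()].
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(included, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       grid = NULL) {
  included <- as.array(included)
  storage.mode(included) <- "logical"
  if (is.null(grid)) grid <- VoxelGrid(dim(included), spacing, origin)
  new("BinaryMask", grid = grid, included = included)
}

#' RigidParams: six-parameter rigid-body pose
#'
#' Translations in mm, rotations in degrees about the world axes at the
#' origin, applied intrinsically in the order Rx, then Ry, then Rz
#' (see [paramsToTransform()]).
#'
#' @slot translation Numeric triple `(tx, ty, tz)` in mm.
#' @slot rotation Numeric triple `(rx, ry, rz)` in degrees, each in
#'   (-180, 180].
#' @export
setClass("RigidParams",
  representation(translation = "numeric", rotation = "numeric"),
  prototype(translation = c(0, 0, 0), rotation = c(0, 0, 0)))

setValidity("RigidParams", function(object) {
  msg <- character()
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be three finite mm values")
  if (length(object@rotation) != 3L || any(!is.finite(object@rotation)) ||
      any(object@rotation <= -180 | object@rotation > 180))
    msg <- c(msg, "rotation angles must be finite degrees in (-180, 180]")
  if (length(msg)) msg else TRUE
})

#' @param tx,ty,tz Translations in mm.
#' @param rx,ry,rz Rotations in degrees.
#' @rdname RigidParams-class
#' @export
RigidParams <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  new("RigidParams", translation = c(tx, ty, tz), rotation = c(rx, ry, rz))
}

#' RigidTransform: homogeneous 4x4 rigid-body matrix
#'
#' @slot matrix 4x4 matrix with orthonormal upper-left 3x3 block of
#'   determinant +1 and last row (0,0,0,1).
#' @export
setClass("RigidTransform", representation(matrix = "matrix"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  msg <- character()
  if (!identical(dim(m), c(4L, 4L))) {
    msg <- c(msg, "matrix must be 4x4")
  } else {
    R <- m[1:3, 1:3]
    if (max(abs(t(R) %*% R - diag(3))) > 1e-8)
      msg <- c(msg, "rotation block must be orthonormal")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation block must have determinant +1")
    if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 0)
      msg <- c(msg, "last row must be (0,0,0,1)")
  }
  if (length(msg)) msg else TRUE
})

#' TrialSet: repeated registration attempts for one unit
#'
#' @slot label Identifier of the patient or user the trials belong to.
#' @slot trials List of [RigidParams-class], at least one.
#' @export
setClass("TrialSet", representation(label = "character", trials = "list"))

setValidity("TrialSet", function(object) {
  msg <- character()
  if (length(object@trials) < 1L)
    msg <- c(msg, "a TrialSet needs at least one trial")
  if (!all(vapply(object@trials, is, logical(1), class2 = "RigidParams")))
    msg <- c(msg, "all trials must be RigidParams")
  if (length(msg)) msg else TRUE
})

#' @param label Unit identifier.
#' @param trials List of [RigidParams-class].
#' @rdname TrialSet-class
#' @export
TrialSet <- function(label, trials) {
  new("TrialSet", label = as.character(label), trials = trials)
}

#' ErrorReport: per-trial spatial errors for one unit
#'
#' @slot label Unit identifier.
#' @slot perTrial Numeric vector of per-trial mean spatial errors (mm, >= 0).
#' @slot nPoints Number of Monte-Carlo points used (0 when errors were
#'   supplied directly).
#' @slot seed Seed used for sampling (NA when not applicable).
#' @export
setClass("ErrorReport",
  representation(label = "character", perTrial = "numeric",
                 nPoints = "integer", seed = "integer"))

setValidity("ErrorReport", function(object) {
  msg <- character()
  if (length(object@perTrial) < 1L || any(object@perTrial < 0))
    msg <- c(msg, "perTrial must be non-negative mm values, at least one")
  if (length(msg)) msg else TRUE
})

#' @param label Unit identifier.
#' @param perTrial Per-trial mean errors in mm.
#' @param nPoints,seed Sampling provenance.
#' @rdname ErrorReport-class
#' @export
ErrorReport <- function(label, perTrial, nPoints = 0L, seed = NA_integer_) {
  new("ErrorReport", label = as.character(label),
      perTrial = as.numeric(perTrial), nPoints = as.integer(nPoints),
      seed = as.integer(seed))
}

#' VariabilitySummary: observer-variability aggregation
#'
#' @slot unitMeans Named numeric vector of per-unit mean errors (mm).
#' @slot kind Either `"intraobserver"` or `"interobserver"`.
#' @export
setClass("VariabilitySummary",
  representation(unitMeans = "numeric", kind = "character"))

setValidity("VariabilitySummary", function(object) {
  msg <- character()
  if (length(object@unitMeans) < 1L)
    msg <- c(msg, "at least one unit mean required")
  if (!object@kind %in% c("intraobserver", "interobserver"))
    msg <- c(msg, "kind must be intraobserver or interobserver")
  if (length(msg)) msg else TRUE
})

#' CombinedVolume: fused structural + vein-label data set
#'
#' @slot grid Shared [VoxelGrid-class].
#' @slot structural Numeric array, the structural channel.
#' @slot veinLabel Logical array: secondary value strictly above the
#'   threshold.
#' @slot threshold The threshold applied to the secondary volume.
#' @export
setClass("CombinedVolume",
  representation(grid = "VoxelGrid", structural = "array",
                 veinLabel = "array", threshold = "numeric"))

setValidity("CombinedVolume", function(object) {
  msg <- character()
  sh <- as.integer(object@grid@shape)
  if (!identical(dim(object@structural), sh) ||
      !identical(dim(object@veinLabel), sh))
    msg <- c(msg, "structural and veinLabel arrays must match the grid shape")
  if (!is.logical(object@veinLabel))
    msg <- c(msg, "veinLabel must be logical")
  if (length(msg)) msg else TRUE
})

#' StandardView: orthographic viewing frame
#'
#' @slot id View number 1-6 (0 for a custom view).
#' @slot direction Unit viewing direction (toward the head).
#' @slot up Unit in-plane "up" vector, orthogonal to direction.
#' @export
setClass("StandardView",
  representation(id = "integer", direction = "numeric", up = "numeric"))

setValidity("StandardView", function(object) {
  msg <- character()
  if (abs(vecNorm(object@direction) - 1) > 1e-9 ||
      abs(vecNorm(object@up) - 1) > 1e-9)
    msg <- c(msg, "direction and up must be unit vectors")
  if (abs(sum(object@direction * object@up)) > 1e-9)
    msg <- c(msg, "direction and up must be orthogonal")
  if (length(msg)) msg else TRUE
})

#' ProjectionImage: orthographic rendering of a volume or polylines
#'
#' @slot pixels 2D numeric array (column u, row v in the view frame).
#' @slot pixelSize Pixel edge length in mm (> 0).
#' @slot view The [StandardView-class] used.
#' @slot origin2d In-plane (u, v) mm coordinate of pixel (1, 1)'s centre.
#' @export
setClass("ProjectionImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 view = "StandardView", origin2d = "numeric"))

setValidity("ProjectionImage", function(object) {
  if (object@pixelSize <= 0) "pixelSize must be positive" else TRUE
})

#' Similarity2D: scale + rotation + translation in the plane
#'
#' @slot scale Dimensionless scale (> 0).
#' @slot rotation Rotation in degrees (counter-clockwise).
#' @slot translation mm pair.
#' @export
setClass("Similarity2D",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric"),
  prototype(scale = 1, rotation = 0, translation = c(0, 0)))

setValidity("Similarity2D", function(object) {
  msg <- character()
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (length(object@translation) != 2L)
    msg <- c(msg, "translation must be an mm pair")
  if (length(msg)) msg else TRUE
})

#' @param scale,rotation,translation See slots.
#' @rdname Similarity2D-class
#' @export
Similarity2D <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  new("Similarity2D", scale = scale, rotation = rotation,
      translation = as.numeric(translation))
}

#' VeinMarkSet: marked 2D vein sections from one source
#'
#' @slot source Either `"reconstruction"` or `"photo"`.
#' @slot sections List of polylines (n x 2 mm matrices, n >= 2).
#' @slot kind Character vector, `"vein"` or `"artery"` per section
#'   (arteries only in photo sets).
#' @slot occlusions List of 2D polygons (photo only) marking regions not
#'   assessable in the photograph.
#' @export
setClass("VeinMarkSet",
  representation(source = "character", sections = "list", kind = "character",
                 occlusions = "list"),
  prototype(occlusions = list()))

setValidity("VeinMarkSet", function(object) {
  msg <- character()
  if (!object@source %in% c("reconstruction", "photo"))
    msg <- c(msg, "source must be reconstruction or photo")
  if (length(object@kind) != length(object@sections))
    msg <- c(msg, "kind must have one entry per section")
  if (!all(object@kind %in% c("vein", "artery")))
    msg <- c(msg, "kind entries must be vein or artery")
  if (object@source == "reconstruction" && any(object@kind == "artery"))
    msg <- c(msg, "arteries are only allowed in photo sets")
  bad <- vapply(object@sections,
                function(s) !is.matrix(s) || nrow(s) < 2 || ncol(s) != 2,
                logical(1))
  if (any(bad)) msg <- c(msg, "each section must be an n x 2 matrix, n >= 2")
  if (length(msg)) msg else TRUE
})

#' @param source,sections,kind,occlusions See slots.
#' @rdname VeinMarkSet-class
#' @export
VeinMarkSet <- function(source, sections, kind = rep("vein", length(sections)),
                        occlusions = list()) {
  new("VeinMarkSet", source = source, sections = sections,
      kind = as.character(kind), occlusions = occlusions)
}

#' CategorySummary: five-category validation bookkeeping
#'
#' Categories: 0 vein in photo and reconstruction (true positive); 1 vein
#' in photo only (false negative); 2 vein in reconstruction only (false
#' positive); 3 reconstruction vein identified as artery in photo; 4 not
#' assessable in photo.
#'
#' @slot counts Integer vector of length 5, counts for categories 0-4.
#' @export
setClass("CategorySummary", representation(counts = "integer"))

setValidity("CategorySummary", function(object) {
  msg <- character()
  if (length(object@counts) != 5L || any(object@counts < 0L))
    msg <- c(msg, "counts must be five non-negative integers")
  if (sum(object@counts) < 1L)
    msg <- c(msg, "at least one categorized section required")
  if (length(msg)) msg else TRUE
})

#' SinusModel: superior sagittal sinus centerline
#'
#' Ordered anterior-to-posterior 3D polyline with arc-length thirds.
#'
#' @slot centerline n x 3 mm matrix, n >= 2.
#' @export
setClass("SinusModel", representation(centerline = "matrix"))

setValidity("SinusModel", function(object) {
  msg <- character()
  if (!is.matrix(object@centerline) || ncol(object@centerline) != 3 ||
      nrow(object@centerline) < 2)
    msg <- c(msg, "centerline must be an n x 3 matrix with n >= 2")
  else if (polylineLength(object@centerline) <= 0)
    msg <- c(msg, "centerline must have positive arc length")
  if (length(msg)) msg else TRUE
})

#' @param centerline n x 3 mm matrix, anterior first.
#' @rdname SinusModel-class
#' @export
SinusModel <- function(centerline) {
  new("SinusModel", centerline = as.matrix(centerline))
}

#' VeinTree: 3D centerline graph of cortical veins
#'
#' Bridging veins are stored as node/edge chains rooted at their sinus
#' junction; each junction record carries the arc-length position along
#' the sinus, the side, the angle group and the vein caliber.
#'
#' @slot nodes n x 3 mm matrix of node positions.
#' @slot edges data.frame with columns `from`, `to` (1-based node ids),
#'   `radius` (mm > 0) and `veinId`.
#' @slot junctions data.frame with columns `node`, `arcPos` (mm along the
#'   sinus), `side` ("L"/"R"), `group`, `veinId`, `caliber` (mm).
#' @slot calibers data.frame with columns `hemisphere`, `trolard`,
#'   `labbe`, `sylvian` (anastomotic vein calibers in mm; NA when not
#'   assessable).
#' @export
setClass("VeinTree",
  representation(nodes = "matrix", edges = "data.frame",
                 junctions = "data.frame", calibers = "data.frame"),
  prototype(junctions = data.frame(), calibers = data.frame()))

setValidity("VeinTree", function(object) {
  msg <- character()
  if (!is.matrix(object@nodes) || ncol(object@nodes) != 3)
    msg <- c(msg, "nodes must be an n x 3 matrix")
  need <- c("from", "to", "radius", "veinId")
  if (nrow(object@edges) && !all(need %in% names(object@edges)))
    msg <- c(msg, "edges needs columns from, to, radius, veinId")
  if (nrow(object@edges) && any(object@edges$radius <= 0))
    msg <- c(msg, "edge radii must be positive")
  if (nrow(object@edges) &&
      (any(object@edges$from < 1) || any(object@edges$to > nrow(object@nodes))))
    msg <- c(msg, "edge node ids out of range")
  if (length(msg)) msg else TRUE
})

#' @param nodes,edges,junctions,calibers See slots.
#' @rdname VeinTree-class
#' @export
VeinTree <- function(nodes, edges, junctions = data.frame(),
                     calibers = data.frame()) {
  nodes <- as.matrix(nodes)
  dimnames(nodes) <- NULL
  new("VeinTree", nodes = nodes, edges = edges,
      junctions = junctions, calibers = calibers)
}

#' PhantomConfig: parameters of the synthetic phantom generator
#'
#' Defaults encode the study conditions the generator emulates: six
#' confluence-angle groups with their means, mean absolute deviations and
#' anatomical ranges; mean bridging-vein counts per sinus third and side;
#' drainage-type frequencies over a cohort of 19; vessel radii; image
#' noise; and the photograph confounder rates.
#'
#' @slot gridShape,spacing,headRadii,shellThickness Volume geometry.
#' @slot angleMeans,angleMADs Named numeric (degrees) per angle group.
#' @slot angleRanges 6 x 2 matrix of truncation bounds (degrees).
#' @slot countMeans 2 x 3 matrix (rows L/R, cols frontal/middle/occipital)
#'   of mean bridging-vein counts; Poisson unless `fixedCounts`.
#' @slot fixedCounts Logical: use `round(countMeans)` deterministically.
#' @slot drainageFreq Named integer frequencies of drainage types I-V.
#' @slot radiusRange Vein radius range (mm).
#' @slot vesselIntensity,noiseSD Angiographic tube intensity and Gaussian
#'   noise SD.
#' @slot photoDropout Fraction of photo veins dropped (truth category 2).
#' @slot photoExtraRate Expected photo-only veins per phantom (category 1).
#' @slot arteryCount Number of recon sections confounded by an artery
#'   trace (category 3).
#' @slot occlusionCount Number of recon sections covered by an occlusion
#'   polygon (category 4).
#' @slot jitterSD SD of i.i.d. Gaussian vertex jitter on marks (mm).
#' @slot misalignment [Similarity2D-class] applied to the photo frame.
#' @export
setClass("PhantomConfig",
  representation(gridShape = "integer", spacing = "numeric",
                 headRadii = "numeric", shellThickness = "numeric",
                 angleMeans = "numeric", angleMADs = "numeric",
                 angleRanges = "matrix", countMeans = "matrix",
                 fixedCounts = "logical", drainageFreq = "integer",
                 radiusRange = "numeric", vesselIntensity = "numeric",
                 noiseSD = "numeric", photoDropout = "numeric",
                 photoExtraRate = "numeric", arteryCount = "integer",
                 occlusionCount = "integer", jitterSD = "numeric",
                 misalignment = "Similarity2D"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (any(object@photoDropout < 0 | object@photoDropout > 1))
    msg <- c(msg, "photoDropout must be in [0, 1]")
  if (any(object@angleMeans <= 0) || any(object@angleMADs < 0))
    msg <- c(msg, "angle means must be positive, MADs non-negative")
  if (!identical(dim(object@countMeans), c(2L, 3L)) ||
      any(object@countMeans < 0))
    msg <- c(msg, "countMeans must be a non-negative 2 x 3 matrix")
  if (!identical(dim(object@angleRanges), c(length(object@angleMeans), 2L)) ||
      any(object@angleRanges[, 2] <= object@angleRanges[, 1]))
    msg <- c(msg, "angleRanges must be an increasing range per group")
  if (any(object@angleMeans < object@angleRanges[, 1]) ||
      any(object@angleMeans > object@angleRanges[, 2]))
    msg <- c(msg, "each angle mean must lie inside its range")
  if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
      diff(object@radiusRange) < 0)
    msg <- c(msg, "radiusRange must be a positive increasing pair")
  if (length(msg)) msg else TRUE
})

#' Phantom: bundle of synthetic inputs plus ground truth
#'
#' @slot structural,angiographic [Volume3D-class] volumes (0 x 0 x 0 when
#'   generated with `volumes = FALSE`).
#' @slot cortexMask [BinaryMask-class] of the cortical shell.
#' @slot sinus [SinusModel-class].
#' @slot tree [VeinTree-class].
#' @slot truth List of ground-truth records (angles, counts, drainage
#'   types, threshold, whether volumes were rasterized).
#' @export
setClass("Phantom",
  representation(structural = "Volume3D", angiographic = "Volume3D",
                 cortexMask = "BinaryMask", sinus = "SinusModel",
                 tree = "VeinTree", truth = "list"))
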