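# Generics for the accessor layer. Slot access stays internal; user code
# goes through these.

#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @export
setGeneric("maskCount", function(x) standardGeneric("maskCount"))

#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @export
setGeneric("rotationAngles", function(x) standardGeneric("rotationAngles"))

#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @export
setGeneric("applyTransform", function(transform, points)
  standardGeneric("applyTransform"))

#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @export
setGeneric("unitMean", function(x) standardGeneric("unitMean"))

#' @export
setGeneric("unitMeans", function(x) standardGeneric("unitMeans"))

#' @export
setGeneric("grandMean", function(x) standardGeneric("grandMean"))

#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @export
setGeneric("thirdBoundaries", function(x) standardGeneric("thirdBoundaries"))

#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @export
setGeneric("categoryPercentages", function(x)
  standardGeneric("categoryPercentages"))

#' @export
setGeneric("veinLabel", function(x) standardGeneric("veinLabel"))

#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @export
setGeneric("sections", function(x) standardGeneric("sections"))
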