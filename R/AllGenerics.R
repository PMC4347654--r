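#' Accessor generics
#'
#' Accessors for the package's S4 containers. Use these instead of reaching
#' into slots.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))

#' @rdname accessors
#' @export
setGeneric("sliceGap", function(object) standardGeneric("sliceGap"))

#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("quantifiableSlices", function(object) standardGeneric("quantifiableSlices"))

#' @rdname accessors
#' @export
setGeneric("contouredSlices", function(object) standardGeneric("contouredSlices"))

#' @rdname accessors
#' @export
setGeneric("enhancementMask", function(object) standardGeneric("enhancementMask"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("methodLabel", function(object) standardGeneric("methodLabel"))

#' @rdname accessors
#' @export
setGeneric("isPercentLvm", function(object) standardGeneric("isPercentLvm"))

#' @rdname accessors
#' @export
setGeneric("msi", function(object) standardGeneric("msi"))

## ---- methods ---------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "ImageStack", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setMethod("sliceThickness", "ImageStack", function(object) object@sliceThickness)

#' @rdname accessors
#' @export
setMethod("sliceGap", "ImageStack", function(object) object@sliceGap)

#' @rdname accessors
#' @export
setMethod("modality", "ImageStack", function(object) object@modality)

#' @rdname accessors
#' @export
setMethod("nSlices", "ImageStack", function(object) dim(object@voxels)[3])

#' @rdname accessors
#' @export
setMethod("nSlices", "MyoMask", function(object) dim(object@mask)[3])

#' @rdname accessors
#' @export
setMethod("maskArray", "MyoMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("quantifiableSlices", "MyoMask", function(object)
  which(object@contoured & !object@excludedApical))

#' @rdname accessors
#' @export
setMethod("contouredSlices", "MyoMask", function(object) which(object@contoured))

#' @rdname accessors
#' @export
setMethod("enhancementMask", "QuantResult", function(object) object@enhancementMask)

#' @rdname accessors
#' @export
setMethod("thresholds", "QuantResult", function(object) object@thresholds)

#' @rdname accessors
#' @export
setMethod("methodLabel", "QuantResult", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("isPercentLvm", "QuantResult", function(object) object@percentLvm)

#' @rdname accessors
#' @export
setMethod("msi", "SalvageResult", function(object) object@msi)
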