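#' Accessors for imaging containers
#'
#' @param object a package container object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameDim", function(object) standardGeneric("frameDim"))
#' @rdname accessors
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))
#' @rdname accessors
#' @export
setGeneric("displayRange", function(object) standardGeneric("displayRange"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("roiName", function(object) standardGeneric("roiName"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("trackedMask", function(object) standardGeneric("trackedMask"))
#' @rdname accessors
#' @export
setGeneric("spatialStep", function(object) standardGeneric("spatialStep"))
#' @rdname accessors
#' @export
setGeneric("shiftDy", function(object) standardGeneric("shiftDy"))
#' @rdname accessors
#' @export
setGeneric("shiftDx", function(object) standardGeneric("shiftDx"))
#' @rdname accessors
#' @export
setGeneric("shiftScore", function(object) standardGeneric("shiftScore"))
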