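# Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("frames", "ChannelStack", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("frameInterval", "ChannelStack", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "RatioStack", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "RatioTrace", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "Kymogram", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "DiameterTrace", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ChannelStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "RatioStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("channelLabel", "ChannelStack", function(object) object@channelLabel)
#' @rdname accessors
#' @export
setMethod("nFrames", "ChannelStack", function(object) dim(object@frames)[1])
#' @rdname accessors
#' @export
setMethod("nFrames", "RatioStack", function(object) dim(object@ratios)[1])
#' @rdname accessors
#' @export
setMethod("frameDim", "ChannelStack", function(object) dim(object@frames)[2:3])
#' @rdname accessors
#' @export
setMethod("frameDim", "RatioStack", function(object) dim(object@ratios)[2:3])
#' @rdname accessors
#' @export
setMethod("ratios", "RatioStack", function(object) object@ratios)
#' @rdname accessors
#' @export
setMethod("displayRange", "RatioStack", function(object) object@displayRange)
#' @rdname accessors
#' @export
setMethod("traceTime", "RatioTrace", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("traceTime", "DiameterTrace", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("traceValues", "RatioTrace", function(object) object@ratio)
#' @rdname accessors
#' @export
setMethod("traceValues", "DiameterTrace", function(object) object@diameter)
#' @rdname accessors
#' @export
setMethod("roiName", "RatioTrace", function(object) object@roiName)
#' @rdname accessors
#' @export
setMethod("roiName", "ROI", function(object) object@name)
#' @rdname accessors
#' @export
setMethod("roiMask", "ROI", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("trackedMask", "DiameterTrace", function(object) object@tracked)
#' @rdname accessors
#' @export
setMethod("spatialStep", "Kymogram", function(object) object@spatialStep)
#' @rdname accessors
#' @export
setMethod("shiftDy", "ShiftVector", function(object) object@dy)
#' @rdname accessors
#' @export
setMethod("shiftDx", "ShiftVector", function(object) object@dx)
#' @rdname accessors
#' @export
setMethod("shiftScore", "ShiftVector", function(object) object@score)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ChannelStack [%s]: %d frames of %d x %d px, %.4g s/frame (%.3g Hz), %.3g um/px\n",
              object@channelLabel, d[1], d[2], d[3], object@frameInterval,
              1 / object@frameInterval, object@pixelSize))
})

setMethod("show", "ShiftVector", function(object) {
  cat(sprintf("ShiftVector: dy = %d, dx = %d px (score %.3f)\n",
              object@dy, object@dx, object@score))
})

setMethod("show", "RatioStack", function(object) {
  d <- dim(object@ratios)
  b <- clipBounds(object@displayRange)
  cat(sprintf("RatioStack: %d frames of %d x %d px, display range [%.3g, %.3g], clip bounds [%.3g, %.3g]\n",
              d[1], d[2], d[3], object@displayRange[1], object@displayRange[2],
              b[1], b[2]))
})

setMethod("show", "RatioTrace", function(object) {
  cat(sprintf("RatioTrace '%s': %d samples over %.3g s (%.3g Hz), ratio range [%.3g, %.3g]\n",
              object@roiName, length(object@ratio),
              max(object@time), 1 / object@frameInterval,
              min(object@ratio, na.rm = TRUE), max(object@ratio, na.rm = TRUE)))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI '%s': %d px of %d x %d\n", object@name,
              sum(object@mask), nrow(object@mask), ncol(object@mask)))
})

setMethod("show", "MeasurementLine", function(object) {
  cat(sprintf("MeasurementLine: (%.1f, %.1f) -> (%.1f, %.1f), band width %d px\n",
              object@p0[1], object@p0[2], object@p1[1], object@p1[2],
              object@bandWidth))
})

setMethod("show", "Kymogram", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("Kymogram: %d frames x %d positions, %.3g um/step, %.4g s/frame\n",
              d[1], d[2], object@spatialStep, object@frameInterval))
})

setMethod("show", "DiameterTrace", function(object) {
  cat(sprintf("DiameterTrace: %d samples, %.1f%% tracked, diameter %.1f-%.1f um\n",
              length(object@diameter), 100 * mean(object@tracked),
              min(object@diameter, na.rm = TRUE),
              max(object@diameter, na.rm = TRUE)))
})

setMethod("show", "PhaseLoop", function(object) {
  cat(sprintf("PhaseLoop: %d points (%s), %d markers\n", length(object@x),
              if (object@closed) "closed" else "open", length(object@markerIdx)))
})

setMethod("show", "BiosensorParams", function(object) {
  cat(sprintf("BiosensorParams: Kd = %.3g M, koff = %.3g /s, kon = %.3g /M/s, R range [%.3g, %.3g]\n",
              object@Kd, object@koff, object@kon, object@Rapo, object@Rsat))
})
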