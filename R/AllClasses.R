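#' @import methods
NULL

#' ChannelStack: a time-ordered single-channel fluorescence image stack
#'
#' Holds a 3-D array of non-negative intensities indexed time x rows x cols
#' together with the acquisition metadata needed downstream: the frame
#' interval in seconds (e.g. 0.02 for 50 Hz wide-field acquisition) and the
#' pixel size in micrometers (e.g. 1.45 um/px).
#'
#' @slot frames numeric 3-D array, time x rows x cols, all values >= 0.
#' @slot frameInterval seconds per frame (> 0).
#' @slot pixelSize micrometers per pixel (> 0).
#' @slot channelLabel one of \code{"donor"}, \code{"fret"}, \code{"generic"}.
#' @export
setClass("ChannelStack",
  representation(frames = "array", frameInterval = "numeric",
                 pixelSize = "numeric", channelLabel = "character"),
  validity = function(object) {
    f <- object@frames
    if (length(dim(f)) != 3L) return("frames must be a 3-D array (time x rows x cols)")
    if (anyNA(f) || any(!is.finite(f))) return("frames must be finite")
    if (any(f < 0)) return("frame intensities must be non-negative")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      return("frameInterval must be a single positive number")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    if (!object@channelLabel %in% c("donor", "fret", "generic"))
      return("channelLabel must be 'donor', 'fret' or 'generic'")
    TRUE
  })

#' Construct a ChannelStack
#'
#' @param frames 3-D numeric array (time x rows x cols) or a list of
#'   equally-shaped matrices (one per frame).
#' @param frameInterval seconds per frame.
#' @param pixelSize micrometers per pixel.
#' @param channelLabel \code{"donor"}, \code{"fret"} or \code{"generic"}.
#' @return A \linkS4class{ChannelStack}.
#' @export
ChannelStack <- function(frames, frameInterval, pixelSize,
                         channelLabel = "generic") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    stopIfNot(length(dims) == 1L, "all frames must have the same shape")
    arr <- array(0, dim = c(length(frames), dims[[1]]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  storage.mode(frames) <- "double"
  new("ChannelStack", frames = frames, frameInterval = frameInterval,
      pixelSize = pixelSize, channelLabel = channelLabel)
}

#' ShiftVector: an estimated integer inter-channel pixel shift
#'
#' @slot dy,dx signed integer shift in pixels (row, column).
#' @slot score normalized cross-correlation value at the peak.
#' @export
setClass("ShiftVector",
  representation(dy = "integer", dx = "integer", score = "numeric"))

#' RatioStack: pixel-wise emission-ratio images
#'
#' Stores R = FRET/donor computed pixel-by-pixel per frame, clipped into
#' \code{[displayRange[1]/4, displayRange[2]*4]} (ratios of near-background
#' pixels diverge; see \code{\link{computeRatioStack}}).
#'
#' @slot ratios 3-D array of clipped ratios.
#' @slot displayRange length-2 numeric, r_min < r_max.
#' @slot frameInterval seconds per frame.
#' @slot pixelSize micrometers per pixel.
#' @export
setClass("RatioStack",
  representation(ratios = "array", displayRange = "numeric",
                 frameInterval = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    dr <- object@displayRange
    if (length(dr) != 2L || !all(is.finite(dr)) || dr[1] >= dr[2])
      return("displayRange must be (r_min, r_max) with r_min < r_max")
    if (length(dim(object@ratios)) != 3L) return("ratios must be 3-D")
    b <- clipBounds(dr)
    r <- range(object@ratios)
    if (r[1] < b[1] - 1e-12 || r[2] > b[2] + 1e-12)
      return("ratio values outside the clip bounds")
    TRUE
  })

#' Clip bounds implied by a display range
#'
#' The clipping rule keeps pixel ratios within a quarter of the minimum
#' displayed ratio and four times the maximum displayed ratio.
#'
#' @param displayRange length-2 numeric (r_min, r_max).
#' @return c(r_min/4, r_max*4).
#' @export
clipBounds <- function(displayRange) {
  c(displayRange[1] / 4, displayRange[2] * 4)
}

#' RatioTrace: an intensity-weighted per-ROI ratio time series
#'
#' @slot time seconds, starting at 0, step = frameInterval.
#' @slot ratio dimensionless emission ratios (NA where a frame had zero
#'   total weight in the ROI).
#' @slot roiName label of the originating ROI.
#' @slot frameInterval seconds per frame.
#' @export
setClass("RatioTrace",
  representation(time = "numeric", ratio = "numeric", roiName = "character",
                 frameInterval = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@ratio))
      return("time and ratio must have equal length")
    r <- object@ratio
    if (any(!is.na(r) & (!is.finite(r) | r <= 0)))
      return("ratio values must be finite and positive (or NA)")
    if (object@frameInterval <= 0) return("frameInterval must be positive")
    TRUE
  })

RatioTrace <- function(ratio, frameInterval, roiName = "roi",
                       time = (seq_along(ratio) - 1) * frameInterval) {
  new("RatioTrace", time = time, ratio = as.numeric(ratio),
      roiName = roiName, frameInterval = frameInterval)
}

#' ROI: a named static region of interest
#'
#' @slot name label, e.g. "atrium" or "ventricle".
#' @slot mask logical matrix matching the frame shape; at least one TRUE.
#' @export
setClass("ROI",
  representation(name = "character", mask = "matrix"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("mask must contain at least one pixel")
    TRUE
  })

#' @rdname ROI-class
#' @param name ROI label.
#' @param mask logical matrix.
#' @export
ROI <- function(name, mask) new("ROI", name = name, mask = mask)

#' MeasurementLine: the line along which a kymogram is built
#'
#' @slot p0,p1 numeric length-2 endpoints (row, col) in pixel coordinates
#'   (1-based, may be fractional).
#' @slot bandWidth odd number of parallel 1-px-spaced lines averaged
#'   perpendicular to the line.
#' @export
setClass("MeasurementLine",
  representation(p0 = "numeric", p1 = "numeric", bandWidth = "integer"),
  validity = function(object) {
    if (length(object@p0) != 2L || length(object@p1) != 2L)
      return("p0 and p1 must be (row, col) pairs")
    if (all(object@p0 == object@p1)) return("p0 and p1 must differ")
    bw <- object@bandWidth
    if (bw < 1L || bw %% 2L == 0L) return("bandWidth must be odd and >= 1")
    TRUE
  })

#' @rdname MeasurementLine-class
#' @param p0,p1 endpoints (row, col).
#' @param bandWidth odd integer >= 1.
#' @export
MeasurementLine <- function(p0, p1, bandWidth = 1L) {
  new("MeasurementLine", p0 = as.numeric(p0), p1 = as.numeric(p1),
      bandWidth = as.integer(bandWidth))
}

#' Kymogram: a space-time intensity map along a measurement line
#'
#' @slot intensities matrix, rows = frames (time), cols = positions along
#'   the line sampled at unit-pixel steps.
#' @slot spatialStep micrometers per kymogram column.
#' @slot frameInterval seconds per row.
#' @export
setClass("Kymogram",
  representation(intensities = "matrix", spatialStep = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    if (object@spatialStep <= 0) return("spatialStep must be positive")
    if (object@frameInterval <= 0) return("frameInterval must be positive")
    TRUE
  })

#' DiameterTrace: tracked ventricular outer-wall diameter over time
#'
#' @slot time seconds.
#' @slot diameter micrometers (interpolated where untracked).
#' @slot tracked logical; FALSE where the wall crossings could not be found
#'   and the value was filled from neighbors.
#' @slot frameInterval seconds per sample.
#' @export
setClass("DiameterTrace",
  representation(time = "numeric", diameter = "numeric", tracked = "logical",
                 frameInterval = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@diameter) != n || length(object@tracked) != n)
      return("time, diameter and tracked must have equal length")
    d <- object@diameter
    if (any(!is.na(d) & d <= 0)) return("diameters must be positive")
    TRUE
  })

#' PhaseLoop: a Lissajous trajectory of two synchronized signals
#'
#' @slot x,y paired samples (e.g. ventricular vs atrial emission ratio).
#' @slot time seconds for each sample.
#' @slot markerIdx indices carrying time markers (arrowheads) at the
#'   configured stride.
#' @slot closed TRUE when the first point was appended to close the loop.
#' @export
setClass("PhaseLoop",
  representation(x = "numeric", y = "numeric", time = "numeric",
                 markerIdx = "integer", closed = "logical"),
  validity = function(object) {
    if (length(object@x) != length(object@y))
      return("x and y must have equal length")
    TRUE
  })

#' BiosensorParams: FRET calcium biosensor binding parameters
#'
#' Defaults describe a troponin-C based ratiometric sensor with in vitro
#' dissociation constant Kd = 2.8 uM and off-rate 2 s^-1; the on-rate is
#' derived as kon = koff/Kd (7e5 M^-1 s^-1 to one significant figure).
#' R_apo and R_sat are the emission-ratio endpoints of the calcium-free and
#' calcium-saturated sensor.
#'
#' @slot Kd mol/L.
#' @slot koff s^-1.
#' @slot kon M^-1 s^-1, always exactly koff/Kd.
#' @slot Rapo,Rsat dimensionless ratio endpoints, Rsat > Rapo > 0.
#' @export
setClass("BiosensorParams",
  representation(Kd = "numeric", koff = "numeric", kon = "numeric",
                 Rapo = "numeric", Rsat = "numeric"),
  validity = function(object) {
    if (object@Kd <= 0 || object@koff <= 0) return("Kd and koff must be positive")
    if (!isTRUE(all.equal(object@kon, object@koff / object@Kd)))
      return("kon must equal koff/Kd")
    if (!(object@Rsat > object@Rapo && object@Rapo > 0))
      return("need Rsat > Rapo > 0")
    TRUE
  })

#' @rdname BiosensorParams-class
#' @param Kd dissociation constant, mol/L.
#' @param koff off-rate, s^-1.
#' @param Rapo,Rsat ratio endpoints of the apo and saturated sensor.
#' @return A \linkS4class{BiosensorParams}; \code{kon} is derived as
#'   \code{koff/Kd}.
#' @export
biosensorParams <- function(Kd = 2.8e-6, koff = 2, Rapo = 1, Rsat = 3) {
  new("BiosensorParams", Kd = Kd, koff = koff, kon = koff / Kd,
      Rapo = Rapo, Rsat = Rsat)
}
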