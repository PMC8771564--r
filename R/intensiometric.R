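# Intensiometric (GCaMP-style) single-channel analysis: EWMA smoothing,
# dF/F0 transformation, and kinetic extraction via the transient detector.

#' Exponentially weighted moving-average smoothing
#'
#' Recursive first-order smoother. With the default convention
#' (\code{convention = "history"}, factor = weight on the previous smoothed
#' value): s_1 = x_1, s_t = factor * s_(t-1) + (1 - factor) * x_t, so a
#' factor of 0.7 smooths heavily and 0 is the identity. The opposite
#' convention (\code{"update"}: factor weights the new sample) is provided
#' because the field uses both.
#'
#' @param x numeric trace.
#' @param factor smoothing factor in [0, 1).
#' @param convention \code{"history"} (default) or \code{"update"}.
#' @return smoothed numeric trace, same length; output range is contained
#'   in the input range (the smoother never overshoots).
#' @export
ewmaSmooth <- function(x, factor = 0.7, convention = c("history", "update")) {
  convention <- match.arg(convention)
  stopIfNot(factor >= 0 && factor < 1, "factor must be in [0, 1)")
  if (convention == "update") factor <- 1 - factor
  x <- as.numeric(x)
  if (factor == 0 || length(x) < 2) return(x)
  s <- as.numeric(stats::filter((1 - factor) * x[-1], factor,
                                method = "recursive", init = x[1]))
  c(x[1], s)
}

#' dF/F0 transformation of a fluorescence trace
#'
#' F0 is the minimum diastolic fluorescence, taken as the global minimum of
#' the (optionally EWMA-smoothed) trace; the output is
#' (F_t - F0)/F0, whose minimum is exactly 0. Invariant to any positive
#' scaling of the raw trace.
#'
#' @param f raw fluorescence values, minimum must be positive.
#' @param smoothFactor apply \code{\link{ewmaSmooth}} with this factor
#'   first; NULL (default) skips smoothing.
#' @return numeric dF/F0 trace.
#' @export
dff <- function(f, smoothFactor = NULL) {
  f <- as.numeric(f)
  if (!is.null(smoothFactor)) f <- ewmaSmooth(f, smoothFactor)
  f0 <- min(f)
  stopIfNot(is.finite(f0) && f0 > 0, "trace minimum must be positive")
  (f - f0) / f0
}

#' Transient kinetics of a dF/F0 trace
#'
#' Delegates to the transient detector and per-cycle kinetics with the
#' diastolic level defined on the dF/F0 scale; reports 10-90% rise and
#' 90-10% decay times per cycle.
#'
#' @param dffTrace numeric dF/F0 values.
#' @param frameInterval seconds per sample.
#' @param minIntervalS,prominenceFraction,windowS detector settings.
#' @return list with \code{cycles} (detector output) and \code{kinetics}
#'   (per-cycle table, see \code{\link{cycleKinetics}}; the ratio columns
#'   hold dF/F0 values).
#' @export
gcampKinetics <- function(dffTrace, frameInterval, minIntervalS = 0.1,
                          prominenceFraction = 0.5, windowS = 1) {
  cyc <- detectTransients(dffTrace, minIntervalS = minIntervalS,
                          prominenceFraction = prominenceFraction,
                          windowS = windowS, frameInterval = frameInterval)
  kin <- cycleKinetics(dffTrace, cyc, frameInterval = frameInterval)
  list(cycles = cyc, kinetics = kin)
}
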