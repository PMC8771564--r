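# Trace conditioning, automatic calcium-transient detection, and per-cycle
# kinetic parameters (diastolic/systolic ratio, amplitude, 10-90% rise and
# 90-10% decay times and slopes, heart rate).

traceInput <- function(trace, frameInterval) {
  if (methods::is(trace, "RatioTrace") || methods::is(trace, "DiameterTrace"))
    list(x = traceValues(trace), dt = frameInterval(trace))
  else {
    stopIfNot(!is.null(frameInterval), "frameInterval needed for a numeric trace")
    list(x = as.numeric(trace), dt = frameInterval)
  }
}

#' Savitzky-Golay smoothing of a trace
#'
#' Least-squares local-polynomial smoothing; a polynomial of degree up to
#' \code{order} passes through the filter unchanged. Endpoints are handled
#' with the asymmetric rows of the Savitzky-Golay projection matrix, so the
#' output has the same length as the input. Smoothing is optional in the
#' analysis pipeline and off by default.
#'
#' @param trace \linkS4class{RatioTrace} or numeric vector.
#' @param window odd window length in samples (default 7).
#' @param order polynomial order < window (default 3).
#' @param frameInterval seconds per sample (numeric input only).
#' @return Smoothed object of the same type as the input.
#' @export
savgolSmooth <- function(trace, window = 7L, order = 3L, frameInterval = NULL) {
  stopIfNot(window %% 2L == 1L, "window must be odd")
  stopIfNot(order < window, "poly order must be smaller than the window")
  x <- if (methods::is(trace, "RatioTrace")) traceValues(trace) else as.numeric(trace)
  stopIfNot(window <= length(x), "window longer than the trace")
  y <- as.numeric(signal::sgolayfilt(x, p = order, n = window))
  if (methods::is(trace, "RatioTrace"))
    RatioTrace(y, frameInterval(trace), roiName = roiName(trace))
  else y
}

#' Automatically detect cardiac transients in a trace
#'
#' Rising edges are detected at upward crossings of a mid-level threshold,
#' diastolic baseline + \code{prominenceFraction} x local amplitude, where
#' baseline and amplitude come from centered rolling minima/maxima over
#' \code{windowS}. Edges closer together than \code{minIntervalS}
#' (refractory period) are merged. Each cycle is assigned the intensity
#' maximum between consecutive rising edges as its systolic peak and the
#' adjacent diastolic minima as its bounds; only cycles bounded by genuine
#' minima on both sides (i.e. not truncated by the recording edges) are
#' returned.
#'
#' @param trace \linkS4class{RatioTrace}, \linkS4class{DiameterTrace} or
#'   numeric vector.
#' @param minIntervalS refractory period, seconds (default 0.1).
#' @param prominenceFraction threshold position between rolling baseline
#'   and rolling maximum (default 0.5).
#' @param windowS rolling-extremum window, seconds (default 1).
#' @param frameInterval seconds per sample (numeric input only).
#' @return data.frame with integer sample indices \code{onset},
#'   \code{peak}, \code{end} (one row per complete cycle; zero rows when
#'   nothing is detected) and attribute \code{frameInterval}.
#' @export
detectTransients <- function(trace, minIntervalS = 0.1,
                             prominenceFraction = 0.5, windowS = 1,
                             frameInterval = NULL) {
  ti <- traceInput(trace, frameInterval)
  x <- ti$x; dt <- ti$dt
  stopIfNot(length(x) * dt > 2 * minIntervalS,
            "trace shorter than twice the refractory period")
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  w <- max(3L, as.integer(round(windowS / dt)))
  lo <- rollExtreme(x, w, min)
  hi <- rollExtreme(x, w, max)
  thr <- lo + prominenceFraction * (hi - lo)
  up <- x > thr
  edges <- which(up[-1] & !up[-length(x)]) + 1L
  out <- data.frame(onset = integer(0), peak = integer(0), end = integer(0))
  attr(out, "frameInterval") <- dt
  if (length(edges) == 0) return(out)
  minGap <- max(1L, as.integer(round(minIntervalS / dt)))
  keep <- edges[1]
  for (e in edges[-1]) if (e - keep[length(keep)] >= minGap) keep <- c(keep, e)
  edges <- keep
  m <- length(edges)
  if (m < 2) return(out)
  # systolic peak of cycle k lives between rising edges k and k+1
  peaks <- vapply(seq_len(m - 1), function(k) {
    seg <- edges[k]:(edges[k + 1] - 1L)
    seg[which.max(x[seg])]
  }, integer(1))
  if (length(peaks) < 3) return(out)
  cyc <- lapply(2:(length(peaks) - 1), function(k) {
    on <- peaks[k - 1] + which.min(x[peaks[k - 1]:peaks[k]]) - 1L
    en <- peaks[k] + which.min(x[peaks[k]:peaks[k + 1]]) - 1L
    c(on, peaks[k], en)
  })
  out <- as.data.frame(do.call(rbind, cyc))
  names(out) <- c("onset", "peak", "end")
  attr(out, "frameInterval") <- dt
  out
}

# Last upward crossing time of `level` on [lo, hi], linearly interpolated;
# sample i sits at time (i-1)*dt.
crossUpLast <- function(x, lo, hi, level, dt) {
  if (hi <= lo) return(NA_real_)
  seg <- lo:(hi - 1L)
  k <- seg[x[seg] < level & x[seg + 1L] >= level]
  if (!length(k)) return(NA_real_)
  i <- max(k)
  (i - 1 + (level - x[i]) / (x[i + 1L] - x[i])) * dt
}

# First downward crossing time of `level` on [lo, hi].
crossDownFirst <- function(x, lo, hi, level, dt) {
  if (hi <= lo) return(NA_real_)
  seg <- lo:(hi - 1L)
  k <- seg[x[seg] >= level & x[seg + 1L] < level]
  if (!length(k)) return(NA_real_)
  i <- min(k)
  (i - 1 + (x[i] - level) / (x[i] - x[i + 1L])) * dt
}

#' Per-cycle kinetic parameters
#'
#' For each detected cycle: diastolic ratio (cycle minimum), systolic ratio
#' (peak), amplitude dR = systolic - diastolic, 10-90% rise time and 90-10%
#' decay time with crossing times located by linear interpolation between
#' bracketing samples (last upward crossing before the peak on the rising
#' limb, first downward crossing after the peak on the falling limb), and
#' the corresponding slopes (ratio change between the 10\% and 90\% levels
#' divided by the time between them). The 10/90\% levels are referenced to
#' each limb's own diastolic end (trace value at the cycle onset for the
#' rising limb, at the cycle end for the falling limb); for well-separated
#' beats both ends equal the cycle minimum and the levels reduce to
#' diastolic + 0.1/0.9 dR, while at high rates where beats fuse (the decay
#' is cut short by the next beat) the falling limb still yields a defined
#' decay time, and the cycle is flagged \code{fused}. Cycles with zero
#' amplitude or unresolvable crossings are dropped with a warning.
#'
#' @param trace \linkS4class{RatioTrace} or numeric vector.
#' @param cycles data.frame from \code{\link{detectTransients}} (or a
#'   single row of it).
#' @param frameInterval seconds per sample (numeric input only).
#' @return data.frame, one row per accepted cycle, with columns
#'   \code{t_onset}, \code{t_peak}, \code{t_end}, \code{diastolic_ratio},
#'   \code{systolic_ratio}, \code{amplitude}, \code{t10_rise},
#'   \code{t90_rise}, \code{t90_decay}, \code{t10_decay},
#'   \code{rise_time_s}, \code{decay_time_s}, \code{rise_slope},
#'   \code{decay_slope}.
#' @export
cycleKinetics <- function(trace, cycles, frameInterval = NULL) {
  ti <- traceInput(trace, frameInterval)
  x <- ti$x; dt <- ti$dt
  rows <- lapply(seq_len(nrow(cycles)), function(k) {
    on <- cycles$onset[k]; pk <- cycles$peak[k]; en <- cycles$end[k]
    dia <- min(x[on:en]); sys <- x[pk]
    amp <- sys - dia
    if (amp <= 0) return(NULL)
    ampRise <- sys - x[on]
    ampDecay <- sys - x[en]
    if (ampRise <= 0 || ampDecay <= 0) return(NULL)
    t10r <- crossUpLast(x, on, pk, x[on] + 0.1 * ampRise, dt)
    t90r <- crossUpLast(x, on, pk, x[on] + 0.9 * ampRise, dt)
    t90d <- crossDownFirst(x, pk, en, x[en] + 0.9 * ampDecay, dt)
    t10d <- if (is.na(t90d)) NA_real_
            else crossDownFirst(x, max(pk, floor(t90d / dt) + 1L), en,
                                x[en] + 0.1 * ampDecay, dt)
    if (anyNA(c(t10r, t90r, t90d, t10d))) return(NULL)
    riseT <- t90r - t10r
    decayT <- t10d - t90d
    if (riseT <= 0 || decayT <= 0) return(NULL)
    fused <- max(x[on], x[en]) - dia > 0.1 * amp
    data.frame(t_onset = (on - 1) * dt, t_peak = (pk - 1) * dt,
               t_end = (en - 1) * dt, diastolic_ratio = dia,
               systolic_ratio = sys, amplitude = amp,
               t10_rise = t10r, t90_rise = t90r,
               t90_decay = t90d, t10_decay = t10d,
               rise_time_s = riseT, decay_time_s = decayT,
               rise_slope = 0.8 * ampRise / riseT,
               decay_slope = 0.8 * ampDecay / decayT,
               fused = fused)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " cycle(s) rejected (zero amplitude or unresolved 10/90% crossings)")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(t_onset = numeric(0), t_peak = numeric(0),
                      t_end = numeric(0), diastolic_ratio = numeric(0),
                      systolic_ratio = numeric(0), amplitude = numeric(0),
                      t10_rise = numeric(0), t90_rise = numeric(0),
                      t90_decay = numeric(0), t10_decay = numeric(0),
                      rise_time_s = numeric(0), decay_time_s = numeric(0),
                      rise_slope = numeric(0), decay_slope = numeric(0),
                      fused = logical(0))
  attr(out, "frameInterval") <- dt
  out
}

#' Heart rate from detected cycles
#'
#' 60 / median peak-to-peak interval by default; the median is robust to a
#' single missed beat. Mean interval available via \code{method}.
#'
#' @param cycles data.frame from \code{\link{detectTransients}}.
#' @param frameInterval seconds per sample; defaults to the attribute
#'   carried by \code{cycles}.
#' @param method \code{"median"} (default) or \code{"mean"} interval.
#' @return beats per minute, or NA (with a warning) for < 2 cycles.
#' @export
heartRate <- function(cycles, frameInterval = NULL, method = c("median", "mean")) {
  method <- match.arg(method)
  if (is.null(frameInterval)) frameInterval <- attr(cycles, "frameInterval")
  if (nrow(cycles) < 2) {
    warning("heart rate undefined for fewer than 2 cycles")
    return(NA_real_)
  }
  iv <- diff(cycles$peak) * frameInterval
  60 / if (method == "median") stats::median(iv) else mean(iv)
}

#' Normalize a ratio trace to its lowest diastolic value
#'
#' Divides every sample by the global minimum of the trace (R/R_Diast), so
#' the normalized minimum is exactly 1. Idempotent up to floating point.
#'
#' @param trace \linkS4class{RatioTrace} or numeric vector with positive
#'   minimum.
#' @return Same type as the input.
#' @export
normalizeToDiastole <- function(trace) {
  x <- if (methods::is(trace, "RatioTrace")) traceValues(trace) else as.numeric(trace)
  m <- min(x, na.rm = TRUE)
  stopIfNot(is.finite(m) && m > 0, "trace minimum must be positive")
  y <- x / m
  if (methods::is(trace, "RatioTrace"))
    RatioTrace(y, frameInterval(trace), roiName = roiName(trace))
  else y
}

#' Summarize a recording over all complete cardiac cycles
#'
#' Arithmetic means of every per-cycle kinetic parameter plus heart rate
#' and cycle count, the per-recording quantities averaged over 5-10 s of
#' continuous recording.
#'
#' @param kinetics data.frame from \code{\link{cycleKinetics}}.
#' @param cycles data.frame from \code{\link{detectTransients}} (for the
#'   heart rate); defaults to peak times in \code{kinetics}.
#' @param durationS recording duration, seconds (optional).
#' @param frameInterval seconds per sample; defaults to the attribute on
#'   \code{kinetics}.
#' @return one-row data.frame: \code{n_cycles}, \code{heart_rate_bpm},
#'   \code{duration_s} and the mean of each kinetic column.
#' @export
summarizeRecording <- function(kinetics, cycles = NULL, durationS = NA,
                               frameInterval = NULL) {
  if (is.null(frameInterval)) frameInterval <- attr(kinetics, "frameInterval")
  n <- nrow(kinetics)
  hr <- if (!is.null(cycles) && nrow(cycles) >= 2)
    heartRate(cycles, frameInterval)
  else if (n >= 2) 60 / stats::median(diff(kinetics$t_peak))
  else NA_real_
  cols <- c("diastolic_ratio", "systolic_ratio", "amplitude",
            "rise_time_s", "decay_time_s", "rise_slope", "decay_slope")
  means <- if (n >= 1) vapply(kinetics[cols], mean, numeric(1))
           else stats::setNames(rep(NA_real_, length(cols)), cols)
  out <- data.frame(n_cycles = n, heart_rate_bpm = hr, duration_s = durationS)
  out[paste0("mean_", cols)] <- as.list(means)
  out
}
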