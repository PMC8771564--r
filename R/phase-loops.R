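# Lissajous phase-loop construction, hysteresis (signed loop area),
# orientation, and atrioventricular rhythm classification.

#' Build a Lissajous phase loop from two synchronized traces
#'
#' Pairs samples of two traces sharing a time base (e.g. ventricular vs
#' atrial emission ratio, or shortening vs ratio) over a time window, with
#' time markers (arrowheads) every \code{markerStrideS} seconds. When the
#' window spans whole cycles the loop can be closed by appending the first
#' point.
#'
#' @param traceX,traceY \linkS4class{RatioTrace}/\linkS4class{DiameterTrace}
#'   objects or numeric vectors on the same time base.
#' @param window c(t_start, t_end) in seconds; NULL uses the full overlap.
#' @param markerStrideS marker spacing, seconds; must be a positive
#'   multiple of the frame interval (e.g. 0.02 marks every frame at 50 Hz
#'   and every 2nd frame at 100 Hz).
#' @param close append the first point to close the loop (default TRUE).
#' @param frameInterval seconds per sample (numeric inputs only).
#' @return A \linkS4class{PhaseLoop}.
#' @export
makeLoop <- function(traceX, traceY, window = NULL, markerStrideS = 0.02,
                     close = TRUE, frameInterval = NULL) {
  tx <- traceInput(traceX, frameInterval)
  ty <- traceInput(traceY, frameInterval)
  stopIfNot(isTRUE(all.equal(tx$dt, ty$dt)) && length(tx$x) == length(ty$x),
            "traces do not share a time base")
  dt <- tx$dt
  strideFrames <- markerStrideS / dt
  stopIfNot(strideFrames >= 1 - 1e-9 &&
              abs(strideFrames - round(strideFrames)) < 1e-6,
            "markerStrideS must be a positive multiple of the frame interval")
  strideFrames <- as.integer(round(strideFrames))
  t <- (seq_along(tx$x) - 1) * dt
  keep <- if (is.null(window)) seq_along(t)
          else which(t >= window[1] - 1e-12 & t <= window[2] + 1e-12)
  stopIfNot(length(keep) >= 3, "window contains fewer than 3 samples")
  x <- tx$x[keep]; y <- ty$x[keep]; tw <- t[keep]
  markers <- seq(1L, length(x), by = strideFrames)
  if (close) {
    x <- c(x, x[1]); y <- c(y, y[1]); tw <- c(tw, tw[1])
  }
  new("PhaseLoop", x = x, y = y, time = tw,
      markerIdx = as.integer(markers), closed = close)
}

#' Signed area of a closed phase loop
#'
#' Shoelace formula; the sign encodes orientation (counter-clockwise
#' positive). The magnitude quantifies the hysteresis between the two
#' signals, in the product of their units.
#'
#' @param loop a closed \linkS4class{PhaseLoop} with >= 3 distinct points.
#' @return signed area.
#' @export
loopArea <- function(loop) {
  stopIfNot(loop@closed, "loop must be closed to compute an area")
  x <- loop@x; y <- loop@y
  n <- length(x)
  stopIfNot(n >= 4, "need at least 3 distinct points")
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Principal-axis orientation of a phase loop
#'
#' Angle (degrees, in (-90, 90]) of the leading principal component of the
#' point cloud relative to the x axis. Reported descriptively; no
#' threshold is attached to it.
#'
#' @param loop a \linkS4class{PhaseLoop}.
#' @return angle in degrees.
#' @export
loopOrientation <- function(loop) {
  m <- cbind(loop@x, loop@y)
  e <- eigen(stats::cov(m))$vectors[, 1]
  ang <- atan2(e[2], e[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Classify atrioventricular activation order
#'
#' Onsets are the 10%-rise times of the detected transients in each
#' chamber. Per beat, each ventricular onset is paired with the nearest
#' atrial onset and the delay Delta = ventricular - atrial is labeled
#' \code{normal} when Delta > w, \code{simultaneous} when |Delta| <= w and
#' \code{ventricle_first} when Delta < -w, with w the simultaneity window
#' (default one frame, e.g. 0.02 s at 50 Hz). Simultaneous or
#' ventricle-first activation suggests failure of the sinoatrial pacemaker
#' with an escape rhythm. The recording label is the majority vote.
#'
#' @param atrial,ventricular per-chamber kinetics data.frames from
#'   \code{\link{cycleKinetics}} (column \code{t10_rise} is used), or
#'   numeric vectors of onset times in seconds.
#' @param simultaneityWindowS the window w, seconds.
#' @param maxPairGapS pairs further apart than this are discarded; default
#'   half the median atrial period.
#' @return list with \code{perBeat} (data.frame t_atrial_s,
#'   t_ventricular_s, delta_s, label) and \code{label} (recording-level
#'   majority).
#' @export
avRhythm <- function(atrial, ventricular, simultaneityWindowS = 0.02,
                     maxPairGapS = NULL) {
  onsets <- function(z) if (is.data.frame(z)) z$t10_rise else as.numeric(z)
  a <- sort(onsets(atrial)); v <- sort(onsets(ventricular))
  stopIfNot(length(a) >= 1 && length(v) >= 1,
            "need at least one onset in each chamber")
  if (is.null(maxPairGapS))
    maxPairGapS <- if (length(a) >= 2) stats::median(diff(a)) / 2 else Inf
  pairs <- lapply(v, function(tv) {
    j <- which.min(abs(a - tv))
    if (abs(a[j] - tv) <= maxPairGapS) c(a[j], tv) else NULL
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) stop("no pairable beats within the pairing window",
                           call. = FALSE)
  delta <- pairs[, 2] - pairs[, 1]
  # tiny tolerance so a delay exactly at the window edge is not pushed
  # over it by floating-point noise
  w <- simultaneityWindowS + 1e-9
  lab <- ifelse(delta > w, "normal",
                ifelse(delta < -w, "ventricle_first", "simultaneous"))
  tab <- table(factor(lab, levels = c("normal", "simultaneous",
                                      "ventricle_first")))
  top <- names(tab)[tab == max(tab)]
  label <- if (length(top) > 1 && "simultaneous" %in% top) "simultaneous"
           else top[1]
  list(perBeat = data.frame(t_atrial_s = pairs[, 1],
                            t_ventricular_s = pairs[, 2],
                            delta_s = delta, label = lab),
       label = label)
}

#' Export phase-loop points to CSV
#'
#' Columns: \code{t}, \code{x}, \code{y}, \code{marker} (logical).
#'
#' @param loop a \linkS4class{PhaseLoop}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLoopCSV <- function(loop, path) {
  marker <- seq_along(loop@x) %in% loop@markerIdx
  utils::write.csv(data.frame(t = loop@time, x = loop@x, y = loop@y,
                              marker = marker),
                   path, row.names = FALSE)
  invisible(path)
}
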