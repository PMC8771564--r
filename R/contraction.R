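# Kymogram construction along a measurement line, outer-wall diameter
# tracking, fractional shortening / fractional area change, and the
# calcium-peak-to-maximal-shortening delay.

# Bilinear interpolation of one frame (matrix) at fractional (row, col)
# coordinates; the caller guarantees 1 <= r <= nrow, 1 <= c <= ncol.
bilinearGather <- function(frame, r, c_) {
  r0 <- clamp(floor(r), 1, nrow(frame) - 1L)
  c0 <- clamp(floor(c_), 1, ncol(frame) - 1L)
  fr <- r - r0; fc <- c_ - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  frame[i00] * (1 - fr) * (1 - fc) + frame[i10] * fr * (1 - fc) +
    frame[i01] * (1 - fr) * fc + frame[i11] * fr * fc
}

#' Build a kymogram along a measurement line
#'
#' For every frame, intensities are sampled by bilinear interpolation at
#' unit-pixel steps along the line from \code{p0} to \code{p1} and averaged
#' over \code{bandWidth} unit-spaced perpendicular offsets. The result is a
#' space-time map in which the moving ventricular walls appear as bright
#' bands.
#'
#' @param stack a \linkS4class{ChannelStack} (typically the FRET channel).
#' @param line a \linkS4class{MeasurementLine}.
#' @return A \linkS4class{Kymogram}; \code{spatialStep} equals the pixel
#'   size (unit-pixel sampling).
#' @export
buildKymogram <- function(stack, line) {
  f <- frames(stack)
  nr <- dim(f)[2]; nc <- dim(f)[3]
  d <- line@p1 - line@p0
  len <- sqrt(sum(d^2))
  u <- d / len                       # unit vector along the line
  perp <- c(-u[2], u[1])             # unit normal
  steps <- seq(0, floor(len))
  offs <- seq(-(line@bandWidth - 1L) / 2, (line@bandWidth - 1L) / 2)
  pr <- outer(line@p0[1] + steps * u[1], offs * perp[1], `+`)
  pc <- outer(line@p0[2] + steps * u[2], offs * perp[2], `+`)
  if (min(pr) < 1 || max(pr) > nr || min(pc) < 1 || max(pc) > nc)
    stop("measurement line (with its band) exits the frame; clip it to rows [1,",
         nr, "], cols [1,", nc, "]", call. = FALSE)
  n <- dim(f)[1]
  ky <- matrix(0, n, length(steps))
  prv <- as.vector(pr); pcv <- as.vector(pc)
  for (i in seq_len(n)) {
    vals <- bilinearGather(f[i, , ], prv, pcv)
    ky[i, ] <- rowMeans(matrix(vals, length(steps), length(offs)))
  }
  new("Kymogram", intensities = ky, spatialStep = pixelSize(stack),
      frameInterval = frameInterval(stack))
}

# One kymogram row -> outer-wall crossing positions (fractional columns),
# or c(NA, NA) when fewer than two interpolable crossings exist.
rowWallCrossings <- function(row, background, thresholdFraction) {
  thr <- background + thresholdFraction * (max(row) - background)
  ab <- row >= thr
  w <- which(ab)
  if (length(w) == 0) return(c(NA_real_, NA_real_))
  i1 <- w[1]; i2 <- w[length(w)]
  if (i1 == 1L || i2 == length(row)) return(c(NA_real_, NA_real_))
  p1 <- i1 - 1 + (thr - row[i1 - 1L]) / (row[i1] - row[i1 - 1L])
  p2 <- i2 + (row[i2] - thr) / (row[i2] - row[i2 + 1L])
  c(p1, p2)
}

#' Track the ventricular outer-wall diameter in a kymogram
#'
#' Per time row, a relative threshold is set at \code{background +
#' thresholdFraction * (row maximum - background)} (the background defaults
#' to the row's 5th percentile), and the diameter is the distance between
#' the outermost upward threshold crossing from the left and the outermost
#' downward crossing from the right, with sub-pixel linear interpolation at
#' the crossings. The outer wall is used because the inner wall gives
#' insufficient contrast. Rows without two crossings are marked untracked
#' and filled by linear interpolation from neighbors; more than
#' \code{maxUntrackedFraction} untracked rows is an error (choose a
#' different line). Optionally the trace is lightly smoothed
#' (Savitzky-Golay, window 5, order 2); the default is no smoothing, since
#' sub-pixel crossing interpolation with band averaging already keeps the
#' tracking noise well below a pixel, while a 5-sample quadratic spans a
#' large part of the systolic dip at 50 Hz and biases per-cycle extrema.
#'
#' @param kymogram a \linkS4class{Kymogram}.
#' @param backgroundLevel fixed background intensity; NULL (default) uses
#'   the per-row \code{backgroundQuantile}.
#' @param backgroundQuantile per-row background quantile (default 0.05).
#' @param thresholdFraction relative threshold height (default 0.5).
#' @param smooth smooth the diameter trace (default FALSE).
#' @param maxUntrackedFraction error above this fraction of untracked rows
#'   (default 0.2).
#' @return A \linkS4class{DiameterTrace} in micrometers.
#' @export
trackOuterWalls <- function(kymogram, backgroundLevel = NULL,
                            backgroundQuantile = 0.05,
                            thresholdFraction = 0.5, smooth = FALSE,
                            maxUntrackedFraction = 0.2) {
  ky <- kymogram@intensities
  n <- nrow(ky)
  cross <- t(vapply(seq_len(n), function(i) {
    row <- ky[i, ]
    bg <- if (is.null(backgroundLevel))
      stats::quantile(row, backgroundQuantile, names = FALSE)
    else backgroundLevel
    rowWallCrossings(row, bg, thresholdFraction)
  }, numeric(2)))
  dpx <- cross[, 2] - cross[, 1]
  tracked <- !is.na(dpx)
  if (mean(!tracked) > maxUntrackedFraction)
    stop(sprintf("%.0f%% of kymogram rows could not be tracked; try a different measurement line",
                 100 * mean(!tracked)), call. = FALSE)
  if (any(!tracked))
    dpx <- zoo::na.approx(dpx, na.rm = FALSE, rule = 2)
  d <- dpx * kymogram@spatialStep
  if (smooth && n >= 5) d <- as.numeric(signal::sgolayfilt(d, p = 2, n = 5))
  new("DiameterTrace", time = (seq_len(n) - 1) * kymogram@frameInterval,
      diameter = d, tracked = tracked,
      frameInterval = kymogram@frameInterval)
}

#' Per-cycle contraction parameters (EDD, ESD, FS)
#'
#' Contraction events are detected on the inverted diameter trace with the
#' same detector as calcium transients. Per cycle, the end-diastolic
#' diameter EDD is the maximum diameter, the end-systolic diameter ESD the
#' minimum, and the fractional shortening FS = (EDD - ESD)/EDD.
#'
#' @param diameterTrace a \linkS4class{DiameterTrace}.
#' @param minIntervalS refractory period for event detection (default 0.1).
#' @param prominenceFraction detector threshold fraction (default 0.5).
#' @param windowS detector rolling window, seconds (default 1).
#' @return data.frame with one row per cycle: \code{onset}, \code{peak}
#'   (sample index of maximal contraction), \code{end}, \code{t_esd_s},
#'   \code{EDD_um}, \code{ESD_um}, \code{FS}.
#' @export
contractionCycles <- function(diameterTrace, minIntervalS = 0.1,
                              prominenceFraction = 0.5, windowS = 1) {
  d <- traceValues(diameterTrace)
  dt <- frameInterval(diameterTrace)
  cyc <- detectTransients(-d, minIntervalS = minIntervalS,
                          prominenceFraction = prominenceFraction,
                          windowS = windowS, frameInterval = dt)
  if (nrow(cyc) == 0) {
    out <- data.frame(onset = integer(0), peak = integer(0), end = integer(0),
                      t_esd_s = numeric(0), EDD_um = numeric(0),
                      ESD_um = numeric(0), FS = numeric(0))
    attr(out, "frameInterval") <- dt
    return(out)
  }
  cyc$t_esd_s <- (cyc$peak - 1) * dt
  cyc$EDD_um <- vapply(seq_len(nrow(cyc)),
                       function(k) max(d[cyc$onset[k]:cyc$end[k]]), numeric(1))
  cyc$ESD_um <- vapply(seq_len(nrow(cyc)),
                       function(k) min(d[cyc$onset[k]:cyc$end[k]]), numeric(1))
  cyc$FS <- (cyc$EDD_um - cyc$ESD_um) / cyc$EDD_um
  attr(cyc, "frameInterval") <- dt
  cyc
}

#' Ventricular area trace from a thresholded mask
#'
#' Otsu's threshold is computed on the time-averaged frame restricted to a
#' bounding box, and the per-frame area is the count of above-threshold
#' pixels times the pixel area. Feeds \code{\link{fractionalAreaChange}}.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param box c(row1, row2, col1, col2) bounding the ventricle; NULL uses
#'   the whole frame.
#' @return numeric vector of areas, um^2 per frame, with attribute
#'   \code{frameInterval}.
#' @export
ventricleAreaTrace <- function(stack, box = NULL) {
  f <- frames(stack)
  if (is.null(box)) box <- c(1L, dim(f)[2], 1L, dim(f)[3])
  sub <- f[, box[1]:box[2], box[3]:box[4], drop = FALSE]
  avg <- apply(sub, c(2, 3), mean)
  mx <- max(sub)
  stopIfNot(mx > 0, "stack is all zero inside the box")
  thr <- EBImage::otsu(EBImage::Image(avg / mx), range = c(0, 1))
  area <- apply(sub / mx >= thr, 1, sum) * pixelSize(stack)^2
  attr(area, "frameInterval") <- frameInterval(stack)
  area
}

#' Per-cycle fractional area change
#'
#' FAC = (end-diastolic area - end-systolic area) / end-diastolic area on
#' cycles detected from the inverted area trace. Cycles with nonpositive
#' end-diastolic area are rejected.
#'
#' @param areaTrace numeric vector of areas (um^2) with a
#'   \code{frameInterval} attribute, e.g. from
#'   \code{\link{ventricleAreaTrace}}.
#' @param frameInterval seconds per sample; defaults to the attribute.
#' @param minIntervalS,prominenceFraction,windowS detector settings.
#' @return data.frame with \code{EDA_um2}, \code{ESA_um2}, \code{FAC} per
#'   cycle.
#' @export
fractionalAreaChange <- function(areaTrace, frameInterval = NULL,
                                 minIntervalS = 0.1,
                                 prominenceFraction = 0.5, windowS = 1) {
  if (is.null(frameInterval)) frameInterval <- attr(areaTrace, "frameInterval")
  a <- as.numeric(areaTrace)
  cyc <- detectTransients(-a, minIntervalS = minIntervalS,
                          prominenceFraction = prominenceFraction,
                          windowS = windowS, frameInterval = frameInterval)
  if (nrow(cyc) == 0)
    return(data.frame(EDA_um2 = numeric(0), ESA_um2 = numeric(0),
                      FAC = numeric(0)))
  eda <- vapply(seq_len(nrow(cyc)),
                function(k) max(a[cyc$onset[k]:cyc$end[k]]), numeric(1))
  esa <- vapply(seq_len(nrow(cyc)),
                function(k) min(a[cyc$onset[k]:cyc$end[k]]), numeric(1))
  ok <- eda > 0
  if (any(!ok)) warning(sum(!ok), " cycle(s) rejected: nonpositive end-diastolic area")
  data.frame(EDA_um2 = eda[ok], ESA_um2 = esa[ok],
             FAC = (eda[ok] - esa[ok]) / eda[ok])
}

#' Delay between the systolic calcium peak and maximal shortening
#'
#' Per cycle, delay = t(minimum diameter) - t(systolic ratio peak), with
#' ratio peaks and diameter minima paired by nearest match within half a
#' median period. Both event times are frame-quantized (raw argmax/argmin).
#'
#' @param ratioTrace ventricular \linkS4class{RatioTrace}.
#' @param diameterTrace \linkS4class{DiameterTrace} on the same time base.
#' @param minIntervalS,prominenceFraction,windowS detector settings applied
#'   to both traces.
#' @return list with \code{mean_s}, \code{sd_s}, \code{n} and the per-cycle
#'   data.frame \code{perCycle} (t_ca_peak_s, t_esd_s, delay_s).
#' @export
caContractionDelay <- function(ratioTrace, diameterTrace, minIntervalS = 0.1,
                               prominenceFraction = 0.5, windowS = 1) {
  stopIfNot(isTRUE(all.equal(frameInterval(ratioTrace),
                             frameInterval(diameterTrace))),
            "ratio and diameter traces must share the time base")
  dt <- frameInterval(ratioTrace)
  caCyc <- detectTransients(ratioTrace, minIntervalS, prominenceFraction,
                            windowS)
  coCyc <- contractionCycles(diameterTrace, minIntervalS,
                             prominenceFraction, windowS)
  stopIfNot(nrow(caCyc) >= 2 && nrow(coCyc) >= 2,
            "need at least 2 matched cycles in both traces")
  if (abs(nrow(caCyc) - nrow(coCyc)) > 1)
    warning("cycle counts differ by more than 1 (", nrow(caCyc), " vs ",
            nrow(coCyc), "); using the matched subset")
  tCa <- (caCyc$peak - 1) * dt
  tCo <- coCyc$t_esd_s
  half <- stats::median(diff(tCa)) / 2
  pair <- lapply(tCa, function(tc) {
    j <- which.min(abs(tCo - tc))
    if (abs(tCo[j] - tc) <= half) c(tc, tCo[j]) else NULL
  })
  pair <- do.call(rbind, pair)
  stopIfNot(!is.null(pair) && nrow(pair) >= 2, "no pairable cycles found")
  delays <- pair[, 2] - pair[, 1]
  list(mean_s = mean(delays), sd_s = stats::sd(delays), n = length(delays),
       perCycle = data.frame(t_ca_peak_s = pair[, 1], t_esd_s = pair[, 2],
                             delay_s = delays))
}

#' Read a measurement line from JSON
#'
#' Format: \code{{"p0": [r, c], "p1": [r, c], "band_width": w}} in 1-based
#' pixel coordinates.
#'
#' @param path JSON file.
#' @return A \linkS4class{MeasurementLine}.
#' @export
readLineJSON <- function(path) {
  stopIfNot(file.exists(path), "line file '", path, "' does not exist")
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  MeasurementLine(s$p0, s$p1, if (is.null(s$band_width)) 1L else s$band_width)
}

#' Write a measurement line to JSON
#'
#' @param line a \linkS4class{MeasurementLine}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLineJSON <- function(line, path) {
  jsonlite::write_json(list(p0 = line@p0, p1 = line@p1,
                            band_width = line@bandWidth),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Export a kymogram as 16-bit TIFF
#'
#' Intensities are linearly rescaled to the full 16-bit range.
#'
#' @param kymogram a \linkS4class{Kymogram}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeKymogramTIFF <- function(kymogram, path) {
  ky <- kymogram@intensities
  rng <- range(ky)
  sc <- if (rng[2] > rng[1]) (ky - rng[1]) / (rng[2] - rng[1]) else ky * 0
  tiff::writeTIFF(sc, path, bits.per.sample = 16L)
  invisible(path)
}
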