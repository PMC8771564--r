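# Pixel-wise emission ratioing with the near-background clipping rule,
# intensity-weighted ROI ratio traces, motion-artifact quantification and
# pseudo-color rendering.

# Clip raw pixel ratios into [r_min/4, r_max*4]; donor = 0 (ratio -> Inf)
# clips to the upper bound.
clipRatios <- function(r, displayRange) {
  b <- clipBounds(displayRange)
  r[!is.finite(r)] <- b[2]
  clamp(r, b[1], b[2])
}

# Weighted quantile by cumulative-weight inversion (type-1 style).
weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# Default display range: 1st-99th percentile of the intensity-weighted
# pixel ratios of the first frame (pixels with zero weight or zero donor
# are ignored).
autoDisplayRange <- function(fret1, donor1) {
  w <- (donor1 + fret1) / 2
  ok <- w > 0 & donor1 > 0
  stopIfNot(any(ok), "cannot derive a display range from an empty first frame")
  r <- fret1[ok] / donor1[ok]
  dr <- weightedQuantile(r, w[ok], c(0.01, 0.99))
  if (dr[1] >= dr[2]) dr <- c(dr[1] * 0.99, dr[1] * 1.01 + 1e-9)
  dr
}

#' Compute the pixel-wise emission-ratio stack
#'
#' R = FRET/donor is computed pixel-by-pixel for every frame. Ratios of
#' pixels near background diverge, so values are clipped into
#' [r_min/4, r_max*4] where (r_min, r_max) is the display range; a zero
#' donor pixel clips to the upper bound. When \code{displayRange} is NULL
#' it is set automatically to the 1st-99th percentile of the
#' intensity-weighted pixel ratios of the first frame.
#'
#' @param fret,donor aligned, equally-shaped \linkS4class{ChannelStack}s.
#' @param displayRange length-2 numeric (r_min, r_max) with r_min < r_max,
#'   or NULL for the automatic percentile range.
#' @return A \linkS4class{RatioStack}.
#' @export
computeRatioStack <- function(fret, donor, displayRange = NULL) {
  stopIfNot(identical(dim(frames(fret)), dim(frames(donor))),
            "fret and donor stacks must have the same shape")
  fF <- frames(fret); fD <- frames(donor)
  if (is.null(displayRange))
    displayRange <- autoDisplayRange(fF[1, , ], fD[1, , ])
  stopIfNot(displayRange[1] < displayRange[2],
            "displayRange minimum must be below its maximum")
  r <- clipRatios(fF / fD, displayRange)
  new("RatioStack", ratios = r, displayRange = as.numeric(displayRange),
      frameInterval = frameInterval(fret), pixelSize = pixelSize(fret))
}

#' Intensity-weighted ROI ratio trace
#'
#' For each frame the ROI ratio is the average of the clipped pixel ratios
#' weighted by the mean channel intensity, R = sum(w_i R_i) / sum(w_i)
#' with w_i = (D_i + F_i)/2. Bright (myocardial) pixels dominate and dim
#' background pixels contribute negligibly, which is what makes a static
#' ROI usable on a moving heart. A frame whose total ROI weight is zero is
#' returned as NA with a warning.
#'
#' @param fret,donor registered \linkS4class{ChannelStack}s.
#' @param roi an \linkS4class{ROI} whose mask matches the frame shape.
#' @param displayRange clipping display range; NULL for automatic (see
#'   \code{\link{computeRatioStack}}).
#' @return A \linkS4class{RatioTrace} with time axis
#'   \code{(frame - 1) * frameInterval}.
#' @export
weightedRoiRatio <- function(fret, donor, roi, displayRange = NULL) {
  stopIfNot(identical(dim(frames(fret)), dim(frames(donor))),
            "fret and donor stacks must have the same shape")
  stopIfNot(all(dim(roiMask(roi)) == frameDim(fret)),
            "ROI mask shape does not match the frame shape")
  fF <- frames(fret); fD <- frames(donor)
  if (is.null(displayRange))
    displayRange <- autoDisplayRange(fF[1, , ], fD[1, , ])
  sel <- which(roiMask(roi))   # matrix index; array element (i, px) = i + (px-1)*n
  n <- dim(fF)[1]
  vals <- vapply(seq_len(n), function(i) {
    D <- fD[(sel - 1L) * n + i]
    F_ <- fF[(sel - 1L) * n + i]
    w <- (D + F_) / 2
    sw <- sum(w)
    if (sw == 0) return(NA_real_)
    r <- clipRatios(F_ / D, displayRange)
    sum(w * r) / sw
  }, numeric(1))
  if (anyNA(vals))
    warning(sum(is.na(vals)), " frame(s) had zero total ROI weight; flagged as NA")
  RatioTrace(vals, frameInterval(fret), roiName = roiName(roi))
}

#' Motion-artifact index: variance of a control trace relative to a test trace
#'
#' Quantifies residual motion artifact as var(control)/var(test), the
#' fraction of the test construct's ratio variance shown by a
#' calcium-insensitive (motion-only) control imaged under comparable
#' conditions. 0 means the control is perfectly still in ratio space; 1
#' means it fluctuates as much as the functional sensor.
#'
#' @param traceTest \linkS4class{RatioTrace} of the functional sensor.
#' @param traceControl \linkS4class{RatioTrace} of the calcium-insensitive
#'   construct.
#' @return Dimensionless variance ratio.
#' @export
motionArtifactIndex <- function(traceTest, traceControl) {
  vt <- stats::var(traceValues(traceTest), na.rm = TRUE)
  vc <- stats::var(traceValues(traceControl), na.rm = TRUE)
  stopIfNot(vt > 0, "test trace has zero variance")
  vc / vt
}

#' Render a ratio frame as a pseudo-color RGB image
#'
#' Hue encodes the emission ratio (linearly over the display range, blue at
#' r_min through red at r_max) and brightness encodes the fluorescence
#' intensity, so dim background pixels fade to black. Deterministic for
#' fixed inputs.
#'
#' @param ratioFrame matrix of ratios.
#' @param intensityFrame matrix of intensities, same shape.
#' @param displayRange length-2 (r_min, r_max) mapped onto the hue axis.
#' @param hueRange hues (HSV, in [0,1]) assigned to r_min and r_max.
#' @return numeric array rows x cols x 3 with RGB values in [0, 1].
#' @export
renderRatioImage <- function(ratioFrame, intensityFrame, displayRange,
                             hueRange = c(2 / 3, 0)) {
  stopIfNot(identical(dim(ratioFrame), dim(intensityFrame)),
            "ratio and intensity frames must have the same shape")
  u <- clamp((ratioFrame - displayRange[1]) /
               (displayRange[2] - displayRange[1]), 0, 1)
  h <- hueRange[1] + u * (hueRange[2] - hueRange[1])
  vmax <- max(intensityFrame)
  v <- if (vmax > 0) intensityFrame / vmax else intensityFrame * 0
  cols <- grDevices::hsv(h = as.vector(h), s = 1, v = as.vector(v))
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim = c(dim(ratioFrame), 3))
}

#' Export ratio traces to CSV
#'
#' Columns: \code{time_s}, \code{ratio}, \code{roi}.
#'
#' @param traces a \linkS4class{RatioTrace} or a list of them.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeTraceCSV <- function(traces, path) {
  if (methods::is(traces, "RatioTrace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = traceTime(tr), ratio = traceValues(tr),
               roi = roiName(tr))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
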