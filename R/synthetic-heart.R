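# Ground-truthed synthetic beating-heart generator: calcium transient
# trains, biosensor binding kinetics, and dual-channel video rendering of a
# two-chambered heart with common-mode motion, autofluorescence and shot
# noise.

#' Physiological presets for the synthetic heart
#'
#' Returns the parameter set describing a larval zebrafish heart at a given
#' developmental stage. Contractile geometry, spontaneous rate and the
#' calcium-to-contraction lag are pinned to reported in vivo physiology:
#' \itemize{
#'   \item \code{"3dpf"}: HR 4.0 Hz, fractional shortening 25.9\%
#'     (EDD 95 um), calcium-peak-to-maximal-shortening lag 17 ms;
#'   \item \code{"5dpf"}: HR 4.6 Hz (faster than at 3 dpf), FS 25.3\%
#'     (EDD 110 um), lag 44 ms;
#'   \item \code{"motion_only"}: the 3 dpf heart expressing a
#'     calcium-insensitive construct — the emission ratio is constant while
#'     all motion remains, emulating a donor-acceptor fusion control. For
#'     this preset autofluorescence and camera offset are zero so the
#'     noiseless ROI ratio is exactly constant.
#' }
#' Free-calcium levels (0.15/1.5 uM diastole/systole), transient shape
#' (tau_rise 20 ms, tau_decay 80 ms), AV delay (60 ms), beat-period jitter
#' (SD 5 ms), photon budget and noise are fixed study conditions documented
#' in the methods vignette. Any field can be overridden through \code{...}
#' (e.g. a smaller \code{EDDum} for compact test frames).
#'
#' @param name preset name.
#' @param ... named overrides of individual fields.
#' @return list of generator parameters (class \code{"heartPreset"}).
#' @export
heartPreset <- function(name = c("3dpf", "5dpf", "motion_only"), ...) {
  name <- match.arg(name)
  p <- list(
    name = name,
    hrHz = 4.0,
    avDelayS = 0.06,
    caToFsLagS = 0.017,
    EDDum = 95,
    ESDum = 95 * (1 - 0.259),
    tauRiseS = 0.02,
    tauDecayS = 0.08,
    diastolicCaM = 1.5e-7,
    systolicCaM = 1.5e-6,
    periodJitterSD = 0.005,
    motionAmp = 0.05,
    autofluorScale = 0.15,
    wallBrightness = 1500,
    atriumBrightness = 1200,
    cameraOffset = 10,
    gaussianSD = 2,
    caInsensitive = FALSE,
    sensor = biosensorParams()
  )
  if (name == "5dpf") {
    p$hrHz <- 4.6
    p$caToFsLagS <- 0.044
    p$EDDum <- 110
    p$ESDum <- 110 * (1 - 0.253)
  } else if (name == "motion_only") {
    p$caInsensitive <- TRUE
    p$autofluorScale <- 0
    p$cameraOffset <- 0
  }
  over <- list(...)
  stopIfNot(all(names(over) %in% names(p)),
            "unknown preset field(s): ",
            paste(setdiff(names(over), names(p)), collapse = ", "))
  p[names(over)] <- over
  stopIfNot(p$ESDum < p$EDDum, "ESD must be smaller than EDD")
  class(p) <- "heartPreset"
  p
}

#' @export
print.heartPreset <- function(x, ...) {
  cat(sprintf("heartPreset '%s': HR %.2g Hz, EDD %.1f um, ESD %.1f um (FS %.1f%%), Ca-to-FS lag %.0f ms%s\n",
              x$name, x$hrHz, x$EDDum, x$ESDum,
              100 * (x$EDDum - x$ESDum) / x$EDDum, 1000 * x$caToFsLagS,
              if (x$caInsensitive) ", Ca-insensitive" else ""))
  invisible(x)
}

# Free-calcium waveform for given onset times on a time grid:
# exponential rise toward the systolic level for 3*tauRise, then
# exponential return toward the diastolic level until the next onset.
caFromOnsets <- function(t, onsets, diastolicCaM, systolicCaM, tauRiseS,
                         tauDecayS) {
  n <- length(t)
  dt <- t[2] - t[1]
  ca <- rep(diastolicCaM, n)
  peaks <- numeric(0)
  cur <- diastolicCaM
  riseDur <- 3 * tauRiseS
  bounds <- c(onsets, t[n] + dt)
  for (k in seq_along(onsets)) {
    i0 <- which.min(abs(t - onsets[k]))
    iPk <- min(n, i0 + as.integer(round(riseDur / dt)))
    if (iPk > i0) {
      seg <- i0:iPk
      ca[seg] <- systolicCaM - (systolicCaM - cur) *
        exp(-(t[seg] - t[i0]) / tauRiseS)
    }
    if (iPk >= n) { peaks <- c(peaks, t[min(iPk, n)]); break }
    peaks <- c(peaks, t[iPk])
    iEnd <- min(n, which.min(abs(t - bounds[k + 1])))
    if (iEnd > iPk) {
      seg <- iPk:iEnd
      pkVal <- ca[iPk]
      ca[seg] <- diastolicCaM + (pkVal - diastolicCaM) *
        exp(-(t[seg] - t[iPk]) / tauDecayS)
      cur <- ca[iEnd]
    }
  }
  list(ca = ca, peaks = peaks)
}

#' Generate a train of calcium transients
#'
#' Periodic pulses at the given rate: exponential rise (time constant
#' \code{tauRiseS}, duration 3 tau) toward the systolic free-calcium level,
#' then exponential return (\code{tauDecayS}) toward the diastolic level.
#' Optional seeded Gaussian jitter on the beat period emulates
#' physiological heart-rate variability.
#'
#' @param hrHz heart rate, Hz.
#' @param durationS trace duration, seconds.
#' @param dt time step, seconds (<= 0.01 for accuracy downstream).
#' @param diastolicCaM,systolicCaM free-calcium levels, mol/L
#'   (systolic > diastolic).
#' @param tauRiseS,tauDecayS rise/decay time constants, seconds.
#' @param periodJitterSD SD of the beat-period jitter, seconds (0 = exactly
#'   periodic).
#' @param firstOnsetS time of the first onset.
#' @param seed RNG seed for the jitter; NULL uses the current stream.
#' @return list: \code{t}, \code{ca} (mol/L), \code{onsets}, \code{peaks}
#'   (seconds).
#' @export
transientTrain <- function(hrHz, durationS, dt = 0.002,
                           diastolicCaM = 1.5e-7, systolicCaM = 1.5e-6,
                           tauRiseS = 0.02, tauDecayS = 0.08,
                           periodJitterSD = 0, firstOnsetS = 0.1,
                           seed = NULL) {
  stopIfNot(systolicCaM > diastolicCaM,
            "systolic calcium must exceed diastolic calcium")
  stopIfNot(dt <= 0.01, "dt must be <= 0.01 s")
  period <- 1 / hrHz
  nBeats <- max(0L, floor((durationS - firstOnsetS) / period) + 1L)
  iv <- rep(period, max(0L, nBeats + 5L))
  if (periodJitterSD > 0)
    iv <- withSeed(seed, pmax(period / 2,
                              iv + stats::rnorm(length(iv), 0, periodJitterSD)))
  onsets <- firstOnsetS + c(0, cumsum(iv))
  onsets <- onsets[onsets < durationS]
  t <- seq(0, durationS, by = dt)
  tr <- caFromOnsets(t, onsets, diastolicCaM, systolicCaM, tauRiseS, tauDecayS)
  list(t = t, ca = tr$ca, onsets = onsets, peaks = tr$peaks)
}

#' Emission ratio of a binding-kinetics-limited FRET biosensor
#'
#' The bound fraction b follows db/dt = kon*Ca*(1 - b) - koff*b. For
#' piecewise-constant Ca each step has the exact solution
#' b(t+dt) = a + (b(t) - a) exp(-r dt) with rate r = kon*Ca + koff and
#' asymptote a = kon*Ca / r, so the integrator is unconditionally stable
#' and matches the analytic step response to floating-point accuracy.
#' The ratio is R = R_apo + b (R_sat - R_apo).
#'
#' @param t uniform time grid, seconds.
#' @param ca free calcium on that grid, mol/L, non-negative and finite.
#' @param params a \linkS4class{BiosensorParams}.
#' @param b0 initial bound fraction; NULL = equilibrium at \code{ca[1]}.
#' @return list: \code{t}, \code{b} (bound fraction), \code{ratio}.
#' @export
biosensorResponse <- function(t, ca, params = biosensorParams(), b0 = NULL) {
  stopIfNot(all(is.finite(ca)) && all(ca >= 0),
            "calcium trace must be finite and non-negative")
  n <- length(t)
  stopIfNot(length(ca) == n, "t and ca must have equal length")
  dt <- t[2] - t[1]
  kon <- params@kon; koff <- params@koff
  r <- kon * ca + koff
  a <- kon * ca / r
  decay <- exp(-r * dt)
  b <- numeric(n)
  b[1] <- if (is.null(b0)) a[1] else b0
  for (i in seq_len(n - 1))
    b[i + 1] <- a[i] + (b[i] - a[i]) * decay[i]
  list(t = t, b = b, ratio = params@Rapo + b * (params@Rsat - params@Rapo))
}

# Contraction drive c(t) in [0, 1] (1 = fully contracted) for dip centers
# tc: smoothstep down over `down` s, a hold of `hold` s carrying a small
# parabolic dip (depth eps) so the minimum stays identifiable at frame
# resolution, then smoothstep release over `up` s.
contractionDrive <- function(t, centers, period, eps = 0.02) {
  down <- 0.24 * period; hold <- 0.16 * period; up <- 0.40 * period
  drive <- numeric(length(t))
  for (tc in centers) {
    t1 <- tc - hold / 2; t0 <- t1 - down
    t2 <- tc + hold / 2; t3 <- t2 + up
    seg <- numeric(length(t))
    inDown <- t >= t0 & t < t1
    seg[inDown] <- (1 - eps) * smoothstep((t[inDown] - t0) / down)
    inHold <- t >= t1 & t <= t2
    seg[inHold] <- 1 - eps * ((t[inHold] - tc) / (hold / 2))^2
    inUp <- t > t2 & t <= t3
    seg[inUp] <- (1 - eps) * smoothstep((t3 - t[inUp]) / up)
    drive <- pmax(drive, seg)
  }
  drive
}

# Elliptical wall-ring intensity in [0, 1]: linear edges of width `edgePx`
# whose 50% level sits exactly on the outer boundary (rho = 1) and on the
# inner boundary rho_in = 1 - wallPx/a, so a half-height threshold crossing
# recovers the nominal outer diameter.
wallRing <- function(rho, a, wallPx, edgePx) {
  outer_ <- clamp((1 - rho) * a / edgePx + 0.5, 0, 1)
  inner <- clamp((rho - (1 - wallPx / a)) * a / edgePx + 0.5, 0, 1)
  outer_ * inner
}

#' Render a ground-truthed dual-channel beating-heart video
#'
#' Draws a two-chambered heart (atrium and ventricle as bright wall
#' annuli) whose ventricular outer diameter oscillates between EDD and ESD
#' along the horizontal axis, with the minimum diameter lagging the
#' ventricular ratio peak by the preset's calcium-to-contraction lag.
#' Atrial activation leads ventricular activation by the AV delay. Total
#' wall fluorescence is split into donor and FRET fractions
#' \code{1/(1+R)} and \code{R/(1+R)} so the pixel emission ratio equals the
#' biosensor ratio exactly while the donor dims and the FRET channel
#' brightens with calcium; a global per-frame factor applies common-mode
#' motion/defocus modulation to everything, static heterogeneous
#' autofluorescence (ratio ~1) sits near the atrium, and seeded
#' Poisson + Gaussian noise emulates the camera.
#'
#' @param preset a \code{\link{heartPreset}} (or preset name).
#' @param durationS recording length, seconds.
#' @param frameRateHz 50, 100 or 200 Hz.
#' @param frameDim frame size c(rows, cols), pixels.
#' @param pixelSizeUm micrometers per pixel (default 1.45).
#' @param seed RNG seed for jitter and noise; the same seed reproduces a
#'   bit-identical video.
#' @param noise apply Poisson + Gaussian camera noise (default TRUE).
#' @param motion apply the common-mode intensity modulation (default TRUE).
#' @param beating set FALSE to freeze all calcium and geometry (every frame
#'   identical in the noiseless case).
#' @param splitView also return the two channels side by side in one
#'   W-View-style stack (donor left).
#' @param returnNoiseless keep the noiseless per-channel frames in the
#'   ground truth.
#' @return list with \code{donor} and \code{fret}
#'   \linkS4class{ChannelStack}s, optional \code{splitView} stack, and
#'   \code{truth}: ground-truth traces (fine-grid and frame-sampled ratios
#'   and diameter), event times (onsets, calcium and ratio peaks,
#'   contraction minima), true FS/HR/delays, suggested chamber ROIs and
#'   measurement line, and the preset.
#' @export
renderHeartVideo <- function(preset = "3dpf", durationS = 10,
                             frameRateHz = 50, frameDim = c(128L, 128L),
                             pixelSizeUm = 1.45, seed = 0L, noise = TRUE,
                             motion = TRUE, beating = TRUE,
                             splitView = FALSE, returnNoiseless = FALSE) {
  if (is.character(preset)) preset <- heartPreset(preset)
  stopIfNot(frameRateHz %in% c(50, 100, 200),
            "frameRateHz must be 50, 100 or 200")
  fi <- 1 / frameRateHz
  nSub <- max(1L, as.integer(ceiling(fi / 0.002)))
  dtFine <- fi / nSub
  nF <- as.integer(round(durationS / fi))
  tFine <- seq(0, (nF - 1L) * fi + (nSub - 1L) * dtFine, by = dtFine)
  frameIdx <- (seq_len(nF) - 1L) * nSub + 1L
  period <- 1 / preset$hrHz

  # --- calcium and sensor dynamics -------------------------------------
  if (beating) {
    atr <- transientTrain(preset$hrHz, durationS, dtFine,
                          preset$diastolicCaM, preset$systolicCaM,
                          preset$tauRiseS, preset$tauDecayS,
                          periodJitterSD = preset$periodJitterSD,
                          firstOnsetS = 0.1, seed = seed)
    caA <- caFromOnsets(tFine, atr$onsets, preset$diastolicCaM,
                        preset$systolicCaM, preset$tauRiseS, preset$tauDecayS)
    vOnsets <- atr$onsets + preset$avDelayS
    vOnsets <- vOnsets[vOnsets < tFine[length(tFine)] - 2 * dtFine]
    caV <- caFromOnsets(tFine, vOnsets, preset$diastolicCaM,
                        preset$systolicCaM, preset$tauRiseS, preset$tauDecayS)
    aOnsets <- atr$onsets
  } else {
    caA <- list(ca = rep(preset$diastolicCaM, length(tFine)), peaks = numeric(0))
    caV <- caA
    aOnsets <- vOnsets <- numeric(0)
  }
  sens <- preset$sensor
  if (preset$caInsensitive) {
    bFix <- sens@kon * preset$diastolicCaM /
      (sens@kon * preset$diastolicCaM + sens@koff)
    rA <- rV <- list(b = rep(bFix, length(tFine)),
                     ratio = rep(sens@Rapo + bFix * (sens@Rsat - sens@Rapo),
                                 length(tFine)))
  } else {
    rA <- biosensorResponse(tFine, caA$ca, sens)
    rV <- biosensorResponse(tFine, caV$ca, sens)
  }

  # Reference peak per beat: the fine-grid ventricular ratio peak (the
  # quantity the analysis itself tracks), or the calcium peak for a
  # calcium-insensitive construct.
  refPeaks <- if (!beating) numeric(0)
    else if (preset$caInsensitive) caV$peaks
    else vapply(vOnsets, function(o) {
      seg <- which(tFine >= o & tFine <= min(o + 0.9 * period,
                                             tFine[length(tFine)]))
      tFine[seg[which.max(rV$ratio[seg])]]
    }, numeric(1))

  # --- geometry and motion ---------------------------------------------
  dipCenters <- refPeaks + preset$caToFsLagS
  drive <- if (beating) contractionDrive(tFine, dipCenters, period) else
    numeric(length(tFine))
  dFine <- preset$EDDum - (preset$EDDum - preset$ESDum) * drive
  atrDip <- if (beating && length(caA$peaks))
    contractionDrive(tFine, caA$peaks + preset$caToFsLagS, period)
  else numeric(length(tFine))
  mCM <- if (motion) 1 + preset$motionAmp * drive else rep(1, length(tFine))

  nr <- frameDim[1]; nc <- frameDim[2]
  vCtr <- c(0.62 * nr, 0.50 * nc)
  aCtr <- c(0.19 * nr, 0.28 * nc)
  aspect <- 1.1                       # ventricle row semi-axis / col semi-axis
  atrBase <- 0.5 * 0.65 * preset$EDDum / pixelSizeUm
  wallPx <- max(3, 0.09 * preset$EDDum / pixelSizeUm)
  atrWallPx <- max(2.5, 0.7 * wallPx)
  edgePx <- 2
  rowG <- matrix(seq_len(nr), nr, nc)
  colG <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  af <- preset$autofluorScale * preset$atriumBrightness *
    exp(-(((rowG - 0.12 * nr)^2 + (colG - 0.55 * nc)^2) / (2 * (0.12 * nr)^2)))

  donor <- array(0, dim = c(nF, nr, nc))
  fret <- array(0, dim = c(nF, nr, nc))
  aEDDpx <- (preset$EDDum / 2) / pixelSizeUm
  # Myocardial fluorophore is conserved: the wall thickens as it shortens
  # so that the annulus area (hence total wall fluorescence) is constant.
  # With inner boundary at rho_in = 1 - w/a the annulus area is
  # proportional to a^2 - (a - w)^2, so w(a) = a - sqrt(a^2 - C) with C
  # pinned by the end-diastolic geometry.
  consC <- 2 * aEDDpx * wallPx - wallPx^2
  consA <- 2 * atrBase * atrWallPx - atrWallPx^2
  for (i in seq_len(nF)) {
    k <- frameIdx[i]
    aV <- (dFine[k] / 2) / pixelSizeUm
    bV <- aspect * aV
    rhoV <- sqrt(((colG - vCtr[2]) / aV)^2 + ((rowG - vCtr[1]) / bV)^2)
    ringV <- wallRing(rhoV, aV, aV - sqrt(aV^2 - consC), edgePx)
    sAt <- 1 - 0.12 * atrDip[k]
    aA <- atrBase * sAt
    rhoA <- sqrt(((colG - aCtr[2]) / aA)^2 + ((rowG - aCtr[1]) / (0.9 * aA))^2)
    ringA <- wallRing(rhoA, aA, aA - sqrt(aA^2 - consA), edgePx)
    RV <- rV$ratio[k]; RA <- rA$ratio[k]
    totV <- preset$wallBrightness * ringV
    totA <- preset$atriumBrightness * ringA
    donor[i, , ] <- mCM[k] * (totV / (1 + RV) + totA / (1 + RA) +
                                af / 2 + preset$cameraOffset)
    fret[i, , ] <- mCM[k] * (totV * RV / (1 + RV) + totA * RA / (1 + RA) +
                               af / 2 + preset$cameraOffset)
  }

  noiseless <- if (returnNoiseless) list(donor = donor, fret = fret)
  if (noise) {
    withSeed(seed + 1L, {
      donor[] <- stats::rpois(length(donor), donor) +
        stats::rnorm(length(donor), 0, preset$gaussianSD)
      fret[] <- stats::rpois(length(fret), fret) +
        stats::rnorm(length(fret), 0, preset$gaussianSD)
    })
    donor <- round(pmax(donor, 0))
    fret <- round(pmax(fret, 0))
  }

  donorStack <- ChannelStack(donor, fi, pixelSizeUm, "donor")
  fretStack <- ChannelStack(fret, fi, pixelSizeUm, "fret")

  # --- ground truth ----------------------------------------------------
  aEDD <- (preset$EDDum / 2) / pixelSizeUm
  roiV <- roiFromEllipse(vCtr, c(aspect * aEDD + 4, aEDD + 4),
                         c(nr, nc), "ventricle")
  roiA <- roiFromEllipse(aCtr, c(0.9 * atrBase + 4, atrBase + 4),
                         c(nr, nc), "atrium")
  margin <- min(aEDD + 12, vCtr[2] - 2, nc - vCtr[2] - 1)
  line <- MeasurementLine(c(vCtr[1], vCtr[2] - margin),
                          c(vCtr[1], vCtr[2] + margin), 3L)
  truth <- list(
    tFine = tFine, caA = caA$ca, caV = caV$ca,
    ratioA = rA$ratio, ratioV = rV$ratio,
    frameTime = (seq_len(nF) - 1L) * fi,
    ratioAFrames = rA$ratio[frameIdx], ratioVFrames = rV$ratio[frameIdx],
    diameterFine = dFine, diameterFrames = dFine[frameIdx],
    atrialOnsets = aOnsets, atrialCaPeaks = caA$peaks,
    ventricularOnsets = vOnsets, ventricularCaPeaks = caV$peaks,
    ventricularRatioPeaks = refPeaks, contractionMinTimes = dipCenters,
    trueFS = (preset$EDDum - preset$ESDum) / preset$EDDum,
    trueHRHz = preset$hrHz, avDelayS = preset$avDelayS,
    caToFsLagS = preset$caToFsLagS,
    roiVentricle = roiV, roiAtrium = roiA, line = line,
    preset = preset, noiseless = noiseless)

  out <- list(donor = donorStack, fret = fretStack, truth = truth)
  if (splitView) {
    sv <- array(0, dim = c(nF, nr, 2L * nc))
    sv[, , seq_len(nc)] <- donor
    sv[, , nc + seq_len(nc)] <- fret
    out$splitView <- ChannelStack(sv, fi, pixelSizeUm, "generic")
  }
  out
}
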