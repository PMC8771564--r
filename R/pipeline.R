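# Pipeline orchestration: in-memory analysis of a registered dual-channel
# recording, a file-based runner with YAML config, and config validation.

defaultConfig <- function() {
  list(
    input = list(split_view = NULL, donor = NULL, fret = NULL,
                 layout = "left-right", donor_side = "left",
                 frame_interval_s = 0.02, pixel_size_um = 1.45),
    roi_file = NULL,
    line_file = NULL,
    out_dir = "ratioheart-out",
    registration = list(max_shift = 10),
    ratio = list(display_range = NULL),
    smoothing = list(enabled = FALSE, window = 7, order = 3),
    detection = list(min_interval_s = 0.1, prominence_fraction = 0.5,
                     window_s = 1.0),
    contraction = list(background_quantile = 0.05, threshold_fraction = 0.5,
                       smooth = FALSE),
    rhythm = list(simultaneity_window_s = NULL),
    loops = list(marker_stride_s = 0.02),
    ventricle_roi = "ventricle",
    atrium_roi = "atrium",
    seed = 0
  )
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[nm] <- user[nm]
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every optional block with its default and collects all problems
#' (not just the first) into the \code{errors} element.
#'
#' @param config named list (e.g. parsed from YAML), possibly empty.
#' @return list with \code{config} (normalized) and \code{errors}
#'   (character vector, empty when valid).
#' @export
validateConfig <- function(config = list()) {
  cfg <- mergeConfig(defaultConfig(), if (is.null(config)) list() else config)
  errs <- character(0)
  addErr <- function(msg) errs <<- c(errs, msg)
  inp <- cfg$input
  if (!is.numeric(inp$frame_interval_s) || inp$frame_interval_s <= 0)
    addErr("input.frame_interval_s must be a positive number")
  if (!is.numeric(inp$pixel_size_um) || inp$pixel_size_um <= 0)
    addErr("input.pixel_size_um must be a positive number")
  if (is.null(inp$split_view) && (is.null(inp$donor) || is.null(inp$fret)))
    addErr("input needs either split_view or both donor and fret paths")
  if (!inp$layout %in% c("left-right", "top-bottom"))
    addErr("input.layout must be 'left-right' or 'top-bottom'")
  for (f in c("split_view", "donor", "fret"))
    if (!is.null(inp[[f]]) && !file.exists(inp[[f]]))
      addErr(paste0("input.", f, " file '", inp[[f]], "' does not exist"))
  for (f in c("roi_file", "line_file"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      addErr(paste0(f, " '", cfg[[f]], "' does not exist"))
  if (is.null(cfg$roi_file)) addErr("roi_file is required")
  sm <- cfg$smoothing
  if (sm$window %% 2 == 0 || sm$order >= sm$window)
    addErr("smoothing.window must be odd and greater than smoothing.order")
  det <- cfg$detection
  if (det$prominence_fraction <= 0 || det$prominence_fraction >= 1)
    addErr("detection.prominence_fraction must be in (0, 1)")
  if (det$min_interval_s <= 0) addErr("detection.min_interval_s must be positive")
  con <- cfg$contraction
  if (con$threshold_fraction <= 0 || con$threshold_fraction >= 1)
    addErr("contraction.threshold_fraction must be in (0, 1)")
  if (cfg$registration$max_shift < 0) addErr("registration.max_shift must be >= 0")
  list(config = cfg, errors = errs)
}

#' Analyze a dual-channel beating-heart recording in memory
#'
#' Runs registration, ratiometry, per-ROI transient detection and
#' kinetics, kymogram wall tracking with fractional shortening, the
#' calcium-to-contraction delay, atrioventricular rhythm classification
#' (when both chamber ROIs are present) and the ventricular-vs-atrial
#' phase loop.
#'
#' @param donor,fret \linkS4class{ChannelStack}s (unregistered is fine).
#' @param rois named list of \linkS4class{ROI}s.
#' @param line \linkS4class{MeasurementLine} for the kymogram, or NULL to
#'   skip contraction analysis.
#' @param config normalized configuration from
#'   \code{\link{validateConfig}} (file paths in it are ignored here);
#'   NULL for defaults.
#' @param ventricleRoi,atriumRoi names of the chamber ROIs in \code{rois}.
#' @return list: \code{shift}, \code{traces}, \code{cycles},
#'   \code{kinetics}, \code{summaries}, \code{kymogram},
#'   \code{diameter}, \code{contraction}, \code{fs}, \code{delay},
#'   \code{rhythm}, \code{loop}, \code{loopArea}.
#' @export
analyzeHeartVideo <- function(donor, fret, rois, line = NULL, config = NULL,
                              ventricleRoi = "ventricle",
                              atriumRoi = "atrium") {
  cfg <- if (is.null(config)) defaultConfig() else config
  det <- cfg$detection
  reg <- registerChannels(donor, fret, maxShift = cfg$registration$max_shift)
  fretAl <- reg$fret
  dr <- cfg$ratio$display_range
  traces <- lapply(rois, function(roi)
    weightedRoiRatio(fretAl, donor, roi, displayRange = dr))
  if (isTRUE(cfg$smoothing$enabled))
    traces <- lapply(traces, savgolSmooth, window = cfg$smoothing$window,
                     order = cfg$smoothing$order)
  cycles <- lapply(traces, detectTransients,
                   minIntervalS = det$min_interval_s,
                   prominenceFraction = det$prominence_fraction,
                   windowS = det$window_s)
  kinetics <- Map(cycleKinetics, traces, cycles)
  durS <- nFrames(donor) * frameInterval(donor)
  summaries <- Map(function(k, cyc) summarizeRecording(k, cyc, durS),
                   kinetics, cycles)

  out <- list(shift = reg$shift, traces = traces, cycles = cycles,
              kinetics = kinetics, summaries = summaries)

  if (!is.null(line)) {
    con <- cfg$contraction
    ky <- buildKymogram(fretAl, line)
    dtr <- trackOuterWalls(ky, backgroundQuantile = con$background_quantile,
                           thresholdFraction = con$threshold_fraction,
                           smooth = isTRUE(con$smooth))
    cc <- contractionCycles(dtr, minIntervalS = det$min_interval_s,
                            prominenceFraction = det$prominence_fraction,
                            windowS = det$window_s)
    out$kymogram <- ky
    out$diameter <- dtr
    out$contraction <- cc
    out$fs <- if (nrow(cc)) list(mean = mean(cc$FS), sd = stats::sd(cc$FS),
                                 n = nrow(cc))
    if (ventricleRoi %in% names(traces) && nrow(cc) >= 2)
      out$delay <- caContractionDelay(traces[[ventricleRoi]], dtr,
                                      minIntervalS = det$min_interval_s,
                                      prominenceFraction = det$prominence_fraction,
                                      windowS = det$window_s)
  }

  if (all(c(ventricleRoi, atriumRoi) %in% names(kinetics)) &&
      nrow(kinetics[[atriumRoi]]) >= 1 && nrow(kinetics[[ventricleRoi]]) >= 1) {
    w <- cfg$rhythm$simultaneity_window_s
    if (is.null(w)) w <- frameInterval(donor)
    out$rhythm <- avRhythm(kinetics[[atriumRoi]], kinetics[[ventricleRoi]],
                           simultaneityWindowS = w)
    out$loop <- makeLoop(traces[[ventricleRoi]], traces[[atriumRoi]],
                         markerStrideS = cfg$loops$marker_stride_s)
    out$loopArea <- loopArea(out$loop)
  }
  out
}

summaryJSON <- function(res) {
  js <- list(
    shift = list(dy = shiftDy(res$shift), dx = shiftDx(res$shift),
                 score = shiftScore(res$shift)),
    rois = lapply(res$summaries, function(s) as.list(s)))
  if (!is.null(res$fs)) js$fractional_shortening <- res$fs
  if (!is.null(res$delay))
    js$ca_contraction_delay <- res$delay[c("mean_s", "sd_s", "n")]
  if (!is.null(res$rhythm)) js$rhythm_label <- res$rhythm$label
  if (!is.null(res$loopArea)) js$loop_area <- res$loopArea
  if (!is.null(res$diameter))
    js$untracked_row_fraction <- mean(!trackedMask(res$diameter))
  js
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads the input stacks (a split-view stack or pre-split donor/FRET
#' stacks), ROI and measurement-line geometry, runs
#' \code{\link{analyzeHeartVideo}}, and writes per-ROI trace and cycle
#' CSVs, the kymogram TIFF, a diameter/FS CSV, loop CSVs, a summary JSON
#' and a log into the output directory. Deterministic given config and
#' input.
#'
#' @param config path to a YAML configuration file, or a named list.
#' @return the \code{\link{analyzeHeartVideo}} result, invisibly, with the
#'   summary attached as \code{$summary}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  vc <- validateConfig(config)
  if (length(vc$errors))
    stop("invalid configuration:\n  - ", paste(vc$errors, collapse = "\n  - "),
         call. = FALSE)
  cfg <- vc$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$out_dir, "log.txt")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logMsg <- function(...) writeLines(paste0(format(Sys.time(), "%H:%M:%S "),
                                            ...), logCon)
  logMsg("ratioheart ", as.character(utils::packageVersion("ratioheart")))
  logMsg("config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"))

  inp <- cfg$input
  if (!is.null(inp$split_view)) {
    stackIn <- readStack(inp$split_view, inp$frame_interval_s,
                         inp$pixel_size_um)
    halves <- splitDualView(stackIn, inp$layout, inp$donor_side)
    donor <- halves$donor; fret <- halves$fret
  } else {
    donor <- readStack(inp$donor, inp$frame_interval_s, inp$pixel_size_um,
                       "donor")
    fret <- readStack(inp$fret, inp$frame_interval_s, inp$pixel_size_um,
                      "fret")
  }
  rois <- readRoiJSON(cfg$roi_file, frameDim(donor))
  line <- if (!is.null(cfg$line_file)) readLineJSON(cfg$line_file)

  res <- tryCatch(
    analyzeHeartVideo(donor, fret, rois, line, cfg,
                      ventricleRoi = cfg$ventricle_roi,
                      atriumRoi = cfg$atrium_roi),
    error = function(e) stop("analysis stage failed: ", conditionMessage(e),
                             call. = FALSE))

  writeTraceCSV(res$traces, file.path(cfg$out_dir, "traces.csv"))
  for (nm in names(res$kinetics))
    utils::write.csv(res$kinetics[[nm]],
                     file.path(cfg$out_dir, paste0("cycles_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(res$cycles))
    logMsg(sprintf("ROI '%s': %d complete cycles", nm, nrow(res$cycles[[nm]])))
  if (!is.null(res$kymogram)) {
    writeKymogramTIFF(res$kymogram, file.path(cfg$out_dir, "kymogram.tif"))
    utils::write.csv(data.frame(time_s = traceTime(res$diameter),
                                diameter_um = traceValues(res$diameter),
                                tracked = trackedMask(res$diameter)),
                     file.path(cfg$out_dir, "diameter.csv"),
                     row.names = FALSE)
    utils::write.csv(res$contraction,
                     file.path(cfg$out_dir, "contraction_cycles.csv"),
                     row.names = FALSE)
    logMsg(sprintf("untracked kymogram rows: %.1f%%",
                   100 * mean(!trackedMask(res$diameter))))
  }
  if (!is.null(res$loop))
    writeLoopCSV(res$loop, file.path(cfg$out_dir, "loop_ventricle_vs_atrium.csv"))
  summary <- summaryJSON(res)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  res$summary <- summary
  invisible(res)
}
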