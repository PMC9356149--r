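# Configuration-driven batch driver running the stages in the fixed order:
# load -> channel selection -> 100 Hz lowpass + line-noise removal ->
# optional resample -> optional bad-channel detection -> wavelet threshold ->
# ERP band filter -> optional segmentation (+ baseline, + within-segment
# interpolation) -> optional segment rejection -> bad-channel interpolation
# -> optional re-reference -> condition split -> outputs + QC tables.

#' Default run configuration
#'
#' Returns the full nested configuration list; it serializes losslessly
#' to/from JSON via [saveRunConfig()] / [loadRunConfig()].
#'
#' @param input_dir directory of input files.
#' @param out_dir output directory.
#' @param markers event markers to segment on (NULL disables segmentation).
#' @return list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function(input_dir = ".", out_dir = "erpflow_out",
                             markers = NULL) {
  structure(list(
    input = list(dir = input_dir, format = "fixture", pattern = "\\.json$"),
    channel_selection = list(mode = "all", names = character(0)),
    line_noise = list(enabled = TRUE, target_freq = 60,
                      extra_freqs = numeric(0)),
    resample = list(target = NULL),
    bad_channels = list(enabled = TRUE),
    wavelet = list(enabled = TRUE, mode = "soft"),
    filter = list(kind = "fir_hamming", highpass = 0.1, lowpass = 30),
    segmentation = list(enabled = !is.null(markers), markers = markers,
                        window = c(-100, 400), timing_offset_ms = 0,
                        baseline = TRUE, baseline_window = c(-100, 0),
                        interpolate_within = FALSE,
                        condition_map = list()),
    rejection = list(enabled = TRUE, criteria = "amplitude",
                     amp_low = -150, amp_high = 150, jp_sd = 3, roi = NULL),
    rereference = list(enabled = FALSE, mode = "average",
                       subset = character(0), recover_prior = FALSE),
    output = list(dir = out_dir, formats = c("txt", "fixture"),
                  save_intermediates = TRUE),
    seed = 1L), class = "RunConfig")
}

#' @rdname defaultRunConfig
#' @param config a \code{RunConfig}.
#' @param path JSON file path.
#' @export
saveRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
loadRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- defaultRunConfig()
  for (sec in names(base)) if (!is.null(cfg[[sec]])) {
    if (is.list(base[[sec]]))
      for (k in names(cfg[[sec]])) base[[sec]][[k]] <- cfg[[sec]][[k]]
    else base[[sec]] <- cfg[[sec]]
  }
  validateRunConfig(base)
  base
}

validateRunConfig <- function(config) {
  ok <- is.list(config$input) && length(config$input$format) == 1 &&
    config$input$format %in% c("fixture", "edf") &&
    config$filter$kind %in% c("fir_hamming", "iir_butterworth")
  if (!ok) stop("config schema violation")
  invisible(TRUE)
}

# reconstruct previously removed bad channels by spherical splines, for a
# continuous recording or per trial of an epoch set
restoreBadChannels <- function(obj, fullLabels, montage, badLabels,
                               settings = splineSettings()) {
  if (!length(badLabels)) return(obj)
  pos <- function(lab) as.matrix(montage[match(lab, montage$label),
                                         c("x", "y", "z")])
  if (is(obj, "EEGRecording")) {
    est <- sphericalSplineInterpolate(obj@data, pos(obj@labels),
                                      pos(badLabels), settings)
    data <- rbind(obj@data, est)
    rownames(data) <- c(obj@labels, badLabels)
    ord <- intersect(fullLabels, rownames(data))
    rec <- newRecording(data[ord, , drop = FALSE], rate = obj@rate,
                        labels = ord,
                        montage = montage[match(ord, montage$label), ],
                        events = obj@events, reference = obj@reference,
                        provenance = obj@provenance)
    return(addProvenance(rec, "interpolate_bad_channels",
                         list(channels = badLabels)))
  }
  ep <- obj
  d <- dim(ep@data)
  ord <- intersect(fullLabels, c(ep@labels, badLabels))
  out <- array(0, dim = c(d[1], length(ord), d[3]))
  oldIdx <- match(ep@labels, ord)
  newIdx <- match(badLabels, ord)
  for (tr in seq_len(d[1])) {
    out[tr, oldIdx, ] <- ep@data[tr, , ]
    out[tr, newIdx, ] <- sphericalSplineInterpolate(
      ep@data[tr, , , drop = TRUE], pos(ep@labels), pos(badLabels), settings)
  }
  ep@data <- out
  ep@labels <- ord
  ep
}

processOneFile <- function(path, config) {
  rec <- readRecording(path, config$input$format)
  rec <- selectChannels(rec, config$channel_selection$mode,
                        config$channel_selection$names)
  fullLabels <- rec@labels
  lengthS <- ncol(rec@data) / rec@rate
  lineFreq <- config$line_noise$target_freq

  rec <- preCleanLowpass(rec)
  linePair <- NULL
  if (isTRUE(config$line_noise$enabled)) {
    ln <- removeLineNoise(rec, lineNoiseSettings(
      target_freq = lineFreq,
      extra_freqs = as.numeric(config$line_noise$extra_freqs)))
    rec <- ln$rec
    linePair <- list(pre = ln$pre, post = ln$rec)
  }
  stage1 <- rec

  if (!is.null(config$resample$target))
    rec <- resampleRecording(rec, config$resample$target)

  badReport <- NULL
  if (isTRUE(config$bad_channels$enabled) && nrow(rec@data) >= 3) {
    badReport <- detectBadChannels(rec, line_freq = lineFreq)
    if (length(badReport$bad))
      rec <- selectChannels(rec, "exclude", badReport$bad)
  }

  wavPair <- NULL
  varRet <- NULL
  if (isTRUE(config$wavelet$enabled)) {
    wv <- waveletClean(rec, waveletSettings(mode = config$wavelet$mode))
    wavPair <- list(pre = rec, post = wv$rec)
    varRet <- varianceRetained(rec, wv$rec)
    rec <- wv$rec
  }

  fspec <- filterSpec(config$filter$kind,
                      highpass = config$filter$highpass,
                      lowpass = config$filter$lowpass)
  rec <- if (fspec$kind == "fir_hamming") firBandpass(rec, fspec)
         else iirBandpass(rec, fspec)

  segsPre <- NA; segsPost <- NA
  perSegInterp <- NULL
  result <- rec
  if (isTRUE(config$segmentation$enabled)) {
    segset <- segmentationSettings(
      window = as.numeric(config$segmentation$window),
      timing_offset_ms = config$segmentation$timing_offset_ms)
    ep <- segmentEvents(rec, config$segmentation$markers, segset)
    if (isTRUE(config$segmentation$baseline))
      ep <- baselineCorrect(ep, as.numeric(config$segmentation$baseline_window))
    if (isTRUE(config$segmentation$interpolate_within) &&
        nrow(rec@montage) && nTrials(ep) >= 3) {
      flags <- fasterEpochChannelFlags(ep)
      ep <- interpolateWithinSegments(ep, flags, rec@montage)
      perSegInterp <- ep@interpolated
    }
    segsPre <- nTrials(ep)
    if (isTRUE(config$rejection$enabled)) {
      pol <- rejectionPolicy(config$rejection$criteria,
                             config$rejection$amp_low,
                             config$rejection$amp_high,
                             config$rejection$jp_sd,
                             config$rejection$roi)
      ep <- rejectSegments(ep, pol)$epochs
    }
    segsPost <- sum(ep@kept)
    if (!is.null(badReport) && length(badReport$bad) && nrow(rec@montage))
      ep <- restoreBadChannels(ep, fullLabels, rec@montage, badReport$bad)
    result <- ep
  } else {
    segsPre <- segsPost <- NA
    if (!is.null(badReport) && length(badReport$bad) && nrow(rec@montage))
      result <- restoreBadChannels(rec, fullLabels, rec@montage,
                                   badReport$bad)
  }

  if (isTRUE(config$rereference$enabled)) {
    if (is(result, "EEGRecording")) {
      result <- rereference(result, config$rereference$mode,
                            config$rereference$subset,
                            config$rereference$recover_prior)
    } else {
      d <- result@data
      refIdx <- if (config$rereference$mode == "average")
        seq_along(result@labels)
      else match(config$rereference$subset, result@labels)
      for (tr in seq_len(dim(d)[1])) {
        trMat <- matrix(d[tr, , ], dim(d)[2], dim(d)[3])
        ref <- colMeans(trMat[refIdx, , drop = FALSE])
        d[tr, , ] <- sweep(trMat, 2, ref, "-")
      }
      result@data <- d
    }
  }

  list(result = result, stage1 = stage1, linePair = linePair,
       wavPair = wavPair, badReport = badReport, varRet = varRet,
       lengthS = lengthS, segsPre = segsPre, segsPost = segsPost,
       perSegInterp = perSegInterp, lineFreq = lineFreq)
}

#' Run the full preprocessing pipeline over a batch of files
#'
#' Executes the fixed stage order per file, saves intermediate and final
#' outputs, writes the data-quality and pipeline-quality CSVs into
#' \code{quality_assessment_outputs}, and echoes the configuration for
#' re-running.  Per-file failures are logged and the batch continues.
#'
#' @param config a \code{RunConfig} (see [defaultRunConfig()]).
#' @return invisibly, a run summary list with per-file artifacts and the QC
#'   tables.
#' @export
runPipeline <- function(config) {
  validateRunConfig(config)
  files <- list.files(config$input$dir, config$input$pattern,
                      full.names = TRUE)
  files <- files[!grepl("_epochs\\.json$", files)]
  outDir <- config$output$dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  qaDir <- file.path(outDir, "quality_assessment_outputs")
  dir.create(qaDir, showWarnings = FALSE)
  saveRunConfig(config, file.path(outDir, "run_config.json"))

  dqRecords <- list(); pqRecords <- list(); results <- list()
  failures <- character(0)
  for (path in files) {
    fname <- basename(path)
    res <- tryCatch(processOneFile(path, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(fname, ": ", conditionMessage(res)))
      next
    }
    stem <- sub("\\.[^.]+$", "", fname)
    fileDir <- file.path(outDir, stem)
    if (isTRUE(config$output$save_intermediates))
      writeStageOutputs(res$stage1, "01_filtered_lineclean", fileDir,
                        "fixture")
    if (is(res$result, "EpochSet")) {
      split <- splitByCondition(res$result,
                                config$segmentation$condition_map)
      for (nm in names(split))
        writeStageOutputs(split[[nm]], paste0("final_", nm), fileDir,
                          config$output$formats)
    } else {
      writeStageOutputs(res$result, "final", fileDir, "fixture")
    }
    dqRecords[[fname]] <- list(
      file = fname, length_s = res$lengthS,
      segs_pre = res$segsPre, segs_post = res$segsPost,
      percent_good = if (is.null(res$badReport)) 100
                     else res$badReport$percent_good,
      interpolated = if (is.null(res$badReport)) character(0)
                     else res$badReport$bad,
      var_retained = res$varRet,
      per_seg_interp = res$perSegInterp)
    pqRecords[[fname]] <- list(
      file = fname, line_freq = res$lineFreq,
      line_pre = res$linePair$pre, line_post = res$linePair$post,
      wav_pre = res$wavPair$pre, wav_post = res$wavPair$post)
    results[[fname]] <- res$result
  }
  dq <- buildDataQualityTable(dqRecords)
  pqRecords <- Filter(function(r) !is.null(r$line_pre) || !is.null(r$wav_pre),
                      pqRecords)
  pq <- if (length(pqRecords)) buildPipelineQualityTable(pqRecords) else NULL
  utils::write.csv(dq, file.path(qaDir, "data_quality.csv"),
                   row.names = FALSE)
  if (!is.null(pq))
    utils::write.csv(pq, file.path(qaDir, "pipeline_quality.csv"),
                     row.names = FALSE)
  if (length(failures))
    writeLines(failures, file.path(outDir, "failures.log"))
  invisible(list(results = results, data_quality = dq,
                 pipeline_quality = pq, failures = failures))
}

#' Generate ERP waveforms, measures, and figures from processed epochs
#'
#' Averages kept trials per file, builds the grand average with standard
#' error and 95% confidence band, computes the measure suite (peaks and
#' latencies per window, global and local extrema, mean amplitudes, AUC, 50%
#' AUC latency; window or zero-crossing bounds), and writes timeseries and
#' measure CSVs plus three figures into \code{generated_ERPs}.
#'
#' @param epochSets named list of [EpochSet-class] objects (one per file),
#'   or a directory containing \code{final_all.json} epoch fixtures from
#'   [runPipeline()].
#' @param out_dir output directory.
#' @param windows list of [measureWindow()] objects.
#' @param bound_mode \code{"window"}, \code{"zero_crossing"} or
#'   \code{"both"}.
#' @param channels,exclude forwarded to [averageTrials()]; \code{exclude}
#'   may also be a two-column data.frame (file, space-separated bad
#'   channels) as derived from the data-quality report.
#' @return invisibly, list with \code{waveforms}, \code{grand} and
#'   \code{measures}.
#' @export
generateErps <- function(epochSets, out_dir = "generated_ERPs",
                         windows = vepMeasureWindows(),
                         bound_mode = c("window", "zero_crossing", "both"),
                         channels = NULL, exclude = character(0)) {
  bound_mode <- match.arg(bound_mode)
  if (is.character(epochSets) && length(epochSets) == 1) {
    paths <- list.files(epochSets, "final_all\\.json$", recursive = TRUE,
                        full.names = TRUE)
    epochSets <- stats::setNames(lapply(paths, readFixtureEpochs),
                                 basename(dirname(paths)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exTab <- NULL
  if (is.data.frame(exclude)) { exTab <- exclude; exclude <- character(0) }
  waveforms <- lapply(names(epochSets), function(nm) {
    ex <- exclude
    if (!is.null(exTab)) {
      hit <- exTab[exTab[[1]] == nm, ]
      if (nrow(hit)) ex <- strsplit(as.character(hit[[2]]), "\\s+")[[1]]
    }
    averageTrials(epochSets[[nm]], channels = channels, exclude = ex)
  })
  names(waveforms) <- names(epochSets)
  waveforms <- Filter(function(w) length(w$values) > 0, waveforms)
  stamp <- format(Sys.Date(), "%Y%m%d")

  grand <- if (length(waveforms) >= 2) grandAverage(waveforms) else NULL
  ts <- data.frame(time_ms = waveforms[[1]]$time,
                   do.call(cbind, lapply(waveforms, `[[`, "values")))
  if (!is.null(grand)) {
    ts$grand_mean <- grand$mean; ts$grand_se <- grand$se
    ts$ci_low <- grand$ci_low; ts$ci_high <- grand$ci_high
  }
  utils::write.csv(ts, file.path(out_dir,
    paste0("generatedERPs_timeseries_", stamp, ".csv")), row.names = FALSE)

  measureOne <- function(w, id) {
    pk <- findPeaks(w, windows)
    rows <- list()
    useWin <- bound_mode %in% c("window", "both")
    useZc <- bound_mode %in% c("zero_crossing", "both")
    if (useWin) for (i in seq_along(windows)) {
      wd <- windows[[i]]
      am <- areaMeasures(w, wd)
      rows[[length(rows) + 1]] <- data.frame(
        file = id, bound = "window", component = names(windows)[i],
        start_ms = wd$start_ms, end_ms = wd$end_ms,
        peak = pk$windows$peak[i], latency = pk$windows$latency[i],
        mean_amplitude = meanAmplitude(w, wd), auc = am$auc,
        auc50 = am$auc50, auc50_latency = am$auc50_latency)
    }
    if (useZc) {
      zw <- zeroCrossingWindows(w)
      for (i in seq_len(nrow(zw))) {
        wd <- c(zw$start_ms[i], zw$end_ms[i])
        if (wd[2] <= wd[1]) next
        am <- areaMeasures(w, wd)
        rows[[length(rows) + 1]] <- data.frame(
          file = id, bound = "zero_crossing", component = paste0("zc", i),
          start_ms = wd[1], end_ms = wd[2],
          peak = NA_real_, latency = NA_real_,
          mean_amplitude = meanAmplitude(w, wd), auc = am$auc,
          auc50 = am$auc50, auc50_latency = am$auc50_latency)
      }
    }
    gl <- areaMeasures(w)
    fmtExtrema <- function(df) paste(sprintf("%.3f@%gms", df$peak,
                                             df$latency), collapse = ";")
    rows[[length(rows) + 1]] <- data.frame(
      file = id, bound = "global", component = "global",
      start_ms = 0, end_ms = max(w$time),
      peak = pk$global$peak[1], latency = pk$global$latency[1],
      mean_amplitude = meanAmplitude(w, c(0, max(w$time))),
      auc = gl$global_abs_auc, auc50 = gl$auc50,
      auc50_latency = gl$auc50_latency)
    out <- do.call(rbind, rows)
    out$local_maxima <- NA_character_
    out$local_minima <- NA_character_
    out$local_maxima[nrow(out)] <- fmtExtrema(pk$local$maxima)
    out$local_minima[nrow(out)] <- fmtExtrema(pk$local$minima)
    out
  }
  measures <- do.call(rbind, c(
    lapply(names(waveforms), function(nm) measureOne(waveforms[[nm]], nm)),
    if (!is.null(grand)) list(measureOne(
      structure(list(values = grand$mean, time = grand$time),
                class = "ERPWaveform"), "grand_average"))))
  utils::write.csv(measures, file.path(out_dir,
    paste0("generatedERPs_measures_", stamp, ".csv")), row.names = FALSE)

  plotTo <- function(file, fun) {
    grDevices::png(file.path(out_dir, file), width = 800, height = 500)
    on.exit(grDevices::dev.off())
    fun()
  }
  tlab <- "time (ms)"; alab <- "amplitude (uV)"
  plotTo("erps_per_file.png", function() {
    graphics::matplot(ts$time_ms, do.call(cbind,
      lapply(waveforms, `[[`, "values")), type = "l", lty = 1,
      xlab = tlab, ylab = alab, main = "Per-file ERPs")
  })
  if (!is.null(grand)) {
    plotTo("erp_grand_average.png", function() {
      graphics::plot(grand$time, grand$mean, type = "l", xlab = tlab,
                     ylab = alab, main = "Grand average +/- SE")
      graphics::lines(grand$time, grand$mean + grand$se, lty = 2)
      graphics::lines(grand$time, grand$mean - grand$se, lty = 2)
    })
    plotTo("erp_combined.png", function() {
      graphics::matplot(ts$time_ms, do.call(cbind,
        lapply(waveforms, `[[`, "values")), type = "l", lty = 1,
        col = "grey70", xlab = tlab, ylab = alab,
        main = "Per-file ERPs and grand average")
      graphics::lines(grand$time, grand$mean, lwd = 2)
    })
  }
  invisible(list(waveforms = waveforms, grand = grand, measures = measures))
}

#' Add the simulated VEP train to a continuous recording
#'
#' Synthesizes the default three-component train at the recording's rate,
#' tiles it across the recording (trimming excess baseline), and writes the
#' embedded recording plus a marker file.
#'
#' @param input path to a continuous recording (fixture or EDF).
#' @param output path of the fixture sidecar to write.
#' @param format input format.
#' @param channels channel names to receive the train (default all).
#' @param mode \code{"include"} or \code{"exclude"} semantics for
#'   \code{channels}.
#' @return invisibly, the embedded [EEGRecording-class].
#' @export
addSimErp <- function(input, output, format = c("fixture", "edf"),
                      channels = NULL, mode = c("include", "exclude")) {
  format <- match.arg(format); mode <- match.arg(mode)
  rec <- readRecording(input, format)
  sim <- synthesizeEpochs(settings = simSettings(rate = rec@rate))
  chans <- if (is.null(channels)) rec@labels
           else if (mode == "include") channels
           else setdiff(rec@labels, channels)
  emb <- embedInBaseline(sim$train, rec, chans)
  writeFixture(emb, output)
  markerPath <- sub("\\.json$", "_markers.csv", output)
  ev <- emb@events
  ev$onset_s <- ev$onset / emb@rate
  utils::write.csv(ev, markerPath, row.names = FALSE)
  invisible(emb)
}
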