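# Data-quality and pipeline-quality report tables.

#' Probe frequencies for the pipeline-quality report
#'
#' @param wavelet_probe_freqs frequencies (Hz) at which pre/post-wavelet
#'   correlations are reported; defaults cover delta through high gamma.
#' @param line_probe_offsets offsets (Hz) around the mains frequency for the
#'   pre/post line-noise correlations.
#' @return list of class \code{QCFrequencies}.
#' @export
qcFrequencies <- function(wavelet_probe_freqs = c(0.5, 1, 2, 5, 8, 12, 20,
                                                  30, 45, 70),
                          line_probe_offsets = -5:5) {
  structure(list(wavelet_probe_freqs = wavelet_probe_freqs,
                 line_probe_offsets = line_probe_offsets),
            class = "QCFrequencies")
}

#' Pre/post correlation within a narrow frequency band
#'
#' Both recordings are zero-phase band-filtered to \code{[f-1, f+1]} Hz
#' (proportional, \code{[f/2, 3f/2]}, below 2 Hz), correlated per channel
#' over time, and the median across channels is returned.
#'
#' @param pre,post [EEGRecording-class] objects of identical shape and rate.
#' @param f centre frequency, Hz.
#' @return median product-moment correlation.
#' @export
bandCorrelation <- function(pre, post, f) {
  if (f >= pre@rate / 2) stop("frequency error: probe at or above Nyquist")
  stopifnot(all(dim(pre@data) == dim(post@data)))
  if (f < 2) { lo <- f / 2; hi <- 1.5 * f } else { lo <- f - 1; hi <- f + 1 }
  hi <- min(hi, pre@rate / 2 * 0.99)
  # narrow probe band: fix the transition width at 1 Hz (or the band width
  # below 2 Hz) rather than using the ERP-filter order heuristic, which is
  # far too loose to separate neighbouring probes
  tb <- min(1, hi - lo)
  taps <- ceiling(3.3 * pre@rate / tb)
  if (taps %% 2 == 0) taps <- taps + 1
  spec <- filterSpec("fir_hamming", highpass = lo, lowpass = hi,
                     order = taps)
  a <- firBandpass(pre, spec)@data
  b <- firBandpass(post, spec)@data
  r <- vapply(seq_len(nrow(a)), function(i) {
    if (stats::sd(a[i, ]) < 1e-12 || stats::sd(b[i, ]) < 1e-12) return(1)
    stats::cor(a[i, ], b[i, ])
  }, 0)
  stats::median(r)
}

#' Percent variance retained by artifact correction
#'
#' Per channel \code{100 (1 - var(pre - post) / var(pre))}, averaged across
#' channels (zero-variance channels excluded).  Strongly negative values are
#' possible when removals are large.
#'
#' @param pre,post [EEGRecording-class] objects of identical shape.
#' @return percentage.
#' @export
varianceRetained <- function(pre, post) {
  stopifnot(all(dim(pre@data) == dim(post@data)))
  v <- vapply(seq_len(nrow(pre@data)), function(i) {
    vp <- stats::var(pre@data[i, ])
    if (vp < 1e-300) return(NA_real_)
    100 * (1 - stats::var(pre@data[i, ] - post@data[i, ]) / vp)
  }, 0)
  mean(v, na.rm = TRUE)
}

#' Build the data-quality report table
#'
#' One row per file with the fixed column set: FileName, File_Length_s,
#' Number_Segs_Pre-Seg_Rej, Number_Segs_Post-Seg_Rej,
#' Percent_Good_Chans_Selected, Interpolated_Chan_IDs,
#' Percent_Var_Retained_Post-Wav, ICA_Metrics, Chans_Interpolated_Per_Seg.
#' Missing stage artifacts yield explicit sentinels and the run continues.
#'
#' @param records list of per-file record lists with (any of) elements
#'   \code{file}, \code{length_s}, \code{segs_pre}, \code{segs_post},
#'   \code{percent_good}, \code{interpolated}, \code{var_retained},
#'   \code{per_seg_interp} (list or \code{NULL} when the within-segment
#'   option was off).
#' @return data.frame with the columns above.
#' @export
buildDataQualityTable <- function(records) {
  orEmpty <- function(x, sentinel = "NA") if (is.null(x)) sentinel else x
  rows <- lapply(records, function(r) {
    perSeg <- if (is.null(r$per_seg_interp)) "N/A"
      else paste(vapply(seq_along(r$per_seg_interp), function(i)
        paste0("seg", i, ":",
               paste(r$per_seg_interp[[i]], collapse = " ")), ""),
        collapse = "; ")
    data.frame(
      FileName = orEmpty(r$file),
      `File_Length_s` = orEmpty(r$length_s, NA_real_),
      `Number_Segs_Pre-Seg_Rej` = orEmpty(r$segs_pre, NA_real_),
      `Number_Segs_Post-Seg_Rej` = orEmpty(r$segs_post, NA_real_),
      `Percent_Good_Chans_Selected` = orEmpty(r$percent_good, NA_real_),
      `Interpolated_Chan_IDs` = if (length(r$interpolated))
        paste(r$interpolated, collapse = " ") else "none",
      `Percent_Var_Retained_Post-Wav` = orEmpty(r$var_retained, NA_real_),
      ICA_Metrics = "NA",
      `Chans_Interpolated_Per_Seg` = perSeg,
      check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the pipeline-quality report table
#'
#' One row per file: pre/post line-noise correlations at the mains
#' frequency and its neighbours (the neighbour set adjusts to the target),
#' and pre/post wavelet correlations broadband plus at the ten probe
#' frequencies.
#'
#' @param records list of per-file lists with \code{file},
#'   \code{line_pre}/\code{line_post} and \code{wav_pre}/\code{wav_post}
#'   [EEGRecording-class] snapshot pairs, and \code{line_freq}.
#' @param freqs a [qcFrequencies()].
#' @return data.frame, one row per file.
#' @export
buildPipelineQualityTable <- function(records, freqs = qcFrequencies()) {
  rows <- lapply(records, function(r) {
    row <- list(FileName = r$file)
    lf <- if (is.null(r$line_freq)) 60 else r$line_freq
    probes <- lf + freqs$line_probe_offsets
    probes <- probes[probes > 0 & probes < r$line_pre@rate / 2]
    for (p in probes)
      row[[sprintf("r_linenoise_%gHz", p)]] <-
        if (is.null(r$line_pre)) NA_real_
        else bandCorrelation(r$line_pre, r$line_post, p)
    row[["r_wavelet_broadband"]] <- if (is.null(r$wav_pre)) NA_real_
      else {
        rr <- vapply(seq_len(nrow(r$wav_pre@data)), function(i)
          stats::cor(r$wav_pre@data[i, ], r$wav_post@data[i, ]), 0)
        stats::median(rr, na.rm = TRUE)
      }
    wp <- freqs$wavelet_probe_freqs
    wp <- wp[wp < r$wav_pre@rate / 2]
    for (p in wp)
      row[[sprintf("r_wavelet_%gHz", p)]] <-
        if (is.null(r$wav_pre)) NA_real_
        else bandCorrelation(r$wav_pre, r$wav_post, p)
    as.data.frame(row, check.names = FALSE)
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  do.call(rbind, rows)
}
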