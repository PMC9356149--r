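#' Accessors for EEGRecording and EpochSet objects
#'
#' Small accessor functions are provided in place of direct slot access:
#' \code{eegData} returns the signal matrix/array, \code{samplingRate} the
#' rate in Hz, \code{channelLabels} the channel names, \code{eventTable} the
#' event-marker data.frame, \code{channelMontage} the electrode positions,
#' \code{priorReference} the online reference name, \code{provenance} the
#' stage log, \code{nTrials}/\code{epochTime}/\code{keptTrials}/
#' \code{trialConditions} the epoch-level metadata.
#'
#' @param x an [EEGRecording-class] or [EpochSet-class] object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("eegData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@rate)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("eventTable", "EEGRecording", function(x) x@events)
#' @rdname accessors
setMethod("channelMontage", "EEGRecording", function(x) x@montage)
#' @rdname accessors
setMethod("priorReference", "EEGRecording", function(x) x@reference)
#' @rdname accessors
setMethod("provenance", "EEGRecording", function(x) x@provenance)
#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("epochTime", "EpochSet", function(x) x@time)
#' @rdname accessors
setMethod("keptTrials", "EpochSet", function(x) x@kept)
#' @rdname accessors
setMethod("trialConditions", "EpochSet", function(x) x@conditions)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nChannels(object), nSamples(object), samplingRate(object),
              nSamples(object) / samplingRate(object)))
  cat(sprintf("  events: %d | montage: %s | reference: %s\n",
              nrow(object@events),
              if (nrow(object@montage)) "present" else "absent",
              object@reference))
  if (length(object@provenance))
    cat("  stages:", paste(vapply(object@provenance, `[[`, "", "stage"),
                           collapse = " -> "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              nTrials(object), nChannels(object), nSamples(object),
              samplingRate(object)))
  if (length(object@time))
    cat(sprintf("  time: [%g, %g] ms | kept: %d/%d\n",
                min(object@time), max(object@time),
                sum(object@kept), nTrials(object)))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

# internal: replace the data matrix, keeping metadata consistent
setRecData <- function(rec, data, stage = NULL, params = list()) {
  rec@data <- data
  rownames(rec@data) <- rec@labels
  if (!is.null(stage)) rec <- addProvenance(rec, stage, params)
  validObject(rec)
  rec
}

addProvenance <- function(rec, stage, params = list()) {
  rec@provenance <- c(rec@provenance,
                      list(list(stage = stage, params = params,
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
  rec
}
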