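#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' An \code{EEGRecording} holds a continuous multichannel EEG signal in
#' microvolts together with its sampling rate, channel labels, optional 3-D
#' electrode montage, event markers, the identity of the prior (online)
#' reference, and a provenance log of the processing stages applied so far.
#'
#' Event onsets are stored internally as 0-based sample indices; all
#' user-facing reports are in seconds or milliseconds.
#'
#' @slot data numeric matrix, channels x samples, in microvolts. Row names
#'   mirror \code{labels}.
#' @slot rate sampling rate in Hz.
#' @slot labels ordered character vector of unique channel names.
#' @slot montage data.frame with columns \code{label}, \code{x}, \code{y},
#'   \code{z} (head-centred, arbitrary units); either zero rows or one row per
#'   channel.
#' @slot events data.frame with columns \code{name} (character), \code{onset}
#'   (0-based integer sample index) and \code{condition} (character, may be
#'   \code{NA}).
#' @slot reference name of the prior online reference, or \code{"unknown"}.
#' @slot provenance list of stage descriptors, each a list with elements
#'   \code{stage}, \code{params} and \code{time}, in execution order.
#'
#' @seealso [newRecording()], [EpochSet-class]
#' @export
setClass("EEGRecording",
  representation(
    data       = "matrix",
    rate       = "numeric",
    labels     = "character",
    montage    = "data.frame",
    events     = "data.frame",
    reference  = "character",
    provenance = "list"
  ),
  prototype(
    data       = matrix(numeric(0), 0, 0),
    rate       = 1,
    labels     = character(0),
    montage    = data.frame(label = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0)),
    events     = data.frame(name = character(0), onset = integer(0),
                            condition = character(0)),
    reference  = "unknown",
    provenance = list()
  )
)

setValidity("EEGRecording", function(object) {
  msgs <- character(0)
  if (nrow(object@data) != length(object@labels))
    msgs <- c(msgs, "number of data rows must equal number of labels")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "channel labels must be unique")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a single positive number")
  ev <- object@events
  if (!all(c("name", "onset", "condition") %in% names(ev)))
    msgs <- c(msgs, "events must have columns name, onset, condition")
  else if (nrow(ev) > 0) {
    if (any(ev$onset < 0) || any(ev$onset != round(ev$onset)))
      msgs <- c(msgs, "event onsets must be non-negative integers")
    if (ncol(object@data) > 0 && any(ev$onset >= ncol(object@data)))
      msgs <- c(msgs, "event onsets must lie within the recording")
  }
  mt <- object@montage
  if (nrow(mt) > 0) {
    if (!all(c("label", "x", "y", "z") %in% names(mt)))
      msgs <- c(msgs, "montage must have columns label, x, y, z")
    else if (!setequal(mt$label, object@labels))
      msgs <- c(msgs, "montage must cover exactly the channel labels")
  }
  if (length(object@reference) != 1L)
    msgs <- c(msgs, "reference must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Set of EEG epochs (segments) around stimulus events
#'
#' An \code{EpochSet} holds segmented EEG as a trials x channels x samples
#' array with a millisecond time axis relative to stimulus onset (including
#' any negative, pre-stimulus baseline portion), per-trial condition labels,
#' per-trial keep/reject flags, and the channels interpolated within each
#' segment.
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot time numeric ms axis relative to stimulus; strictly increasing with
#'   step 1000/rate.
#' @slot labels channel names.
#' @slot rate sampling rate in Hz.
#' @slot conditions character, one per trial (the event marker name or an
#'   assigned condition label).
#' @slot kept logical, one per trial; \code{FALSE} marks rejected trials.
#' @slot interpolated list, one character vector per trial, naming channels
#'   interpolated within that segment.
#' @slot notes character vector of processing notations (for example that no
#'   trials were found for a requested marker).
#'
#' @seealso [segmentEvents()], [EEGRecording-class]
#' @export
setClass("EpochSet",
  representation(
    data         = "array",
    time         = "numeric",
    labels       = "character",
    rate         = "numeric",
    conditions   = "character",
    kept         = "logical",
    interpolated = "list",
    notes        = "character"
  ),
  prototype(
    data         = array(numeric(0), dim = c(0, 0, 0)),
    time         = numeric(0),
    labels       = character(0),
    rate         = 1,
    conditions   = character(0),
    kept         = logical(0),
    interpolated = list(),
    notes        = character(0)
  )
)

setValidity("EpochSet", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L)
    msgs <- c(msgs, "data must be a trials x channels x samples array")
  else {
    if (d[2] != length(object@labels))
      msgs <- c(msgs, "second dimension must match number of labels")
    if (d[3] != length(object@time))
      msgs <- c(msgs, "third dimension must match length of time axis")
    if (d[1] != length(object@kept))
      msgs <- c(msgs, "kept flags must have one entry per trial")
    if (d[1] != length(object@conditions))
      msgs <- c(msgs, "conditions must have one entry per trial")
    if (length(object@interpolated) != d[1])
      msgs <- c(msgs, "interpolated must have one entry per trial")
  }
  if (length(object@time) > 1) {
    step <- diff(object@time)
    if (any(step <= 0))
      msgs <- c(msgs, "time axis must be strictly increasing")
    if (max(abs(step - 1000 / object@rate)) > 1e-6)
      msgs <- c(msgs, "time axis step must equal 1000/rate ms")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate, Hz.
#' @param labels channel names; defaults to the row names of \code{data} or
#'   \code{E1..En}.
#' @param montage optional data.frame with columns \code{label,x,y,z}.
#' @param events optional data.frame with columns \code{name,onset} and
#'   optionally \code{condition}; onsets are 0-based sample indices.
#' @param reference prior online reference name, default \code{"unknown"}.
#' @param provenance list of prior stage descriptors.
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- newRecording(matrix(rnorm(1000), 4), rate = 250)
#' nChannels(rec)
#' @export
newRecording <- function(data, rate, labels = NULL, montage = NULL,
                         events = NULL, reference = "unknown",
                         provenance = list()) {
  data <- as.matrix(data)
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
      labels <- paste0("E", seq_len(nrow(data)))
  }
  rownames(data) <- labels
  if (is.null(montage))
    montage <- data.frame(label = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0))
  events <- normalizeEvents(events)
  new("EEGRecording", data = data, rate = as.numeric(rate),
      labels = as.character(labels), montage = as.data.frame(montage),
      events = events, reference = reference, provenance = provenance)
}

normalizeEvents <- function(events) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0)
    return(data.frame(name = character(0), onset = integer(0),
                      condition = character(0)))
  events <- as.data.frame(events)
  if (is.null(events$condition)) events$condition <- NA_character_
  data.frame(name = as.character(events$name),
             onset = as.integer(round(events$onset)),
             condition = as.character(events$condition))
}
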