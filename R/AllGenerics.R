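#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("channelMontage", function(x) standardGeneric("channelMontage"))

#' @rdname accessors
#' @export
setGeneric("priorReference", function(x) standardGeneric("priorReference"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("epochTime", function(x) standardGeneric("epochTime"))

#' @rdname accessors
#' @export
setGeneric("keptTrials", function(x) standardGeneric("keptTrials"))

#' @rdname accessors
#' @export
setGeneric("trialConditions", function(x) standardGeneric("trialConditions"))
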