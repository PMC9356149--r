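#' Read a continuous EEG recording from disk
#'
#' Reads either an EDF/EDF+ file or the package's plain-text fixture format
#' (a tab-separated channels x samples matrix next to a JSON sidecar holding
#' rate, labels, events, montage and reference).  Events are populated from
#' the EDF+ annotations channel or from the sidecar; the stored sampling rate
#' and channel order are preserved.
#'
#' @param path path to the EDF file or to the fixture JSON sidecar.
#' @param format \code{"edf"} or \code{"fixture"}.
#' @param montage_path optional path to an SFP-style whitespace-separated
#'   electrode position file with columns \code{name x y z}.
#' @return an [EEGRecording-class].
#' @examples
#' rec <- newRecording(matrix(sin(1:1000 / 10), 4, 250, byrow = TRUE), 250)
#' f <- file.path(tempdir(), "rec.json")
#' writeFixture(rec, f)
#' rec2 <- readRecording(f, "fixture")
#' @export
readRecording <- function(path, format = c("fixture", "edf"),
                          montage_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  rec <- switch(format,
                fixture = readFixtureRecording(path),
                edf     = readEdf(path))
  if (!is.null(montage_path)) {
    mt <- readMontage(montage_path)
    if (!setequal(mt$label, rec@labels))
      stop("montage error: electrode names do not match channel labels")
    rec@montage <- mt[match(rec@labels, mt$label), , drop = FALSE]
    rownames(rec@montage) <- NULL
  }
  validObject(rec)
  rec
}

#' Read an SFP-style electrode position file
#'
#' @param path whitespace-separated text file with columns
#'   \code{name x y z}.
#' @return data.frame with columns \code{label,x,y,z}.
#' @export
readMontage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                           colClasses = c("character", "numeric", "numeric", "numeric"))
  tab
}

# ---- fixture format -------------------------------------------------------

#' Write a recording or epoch set as a plain-text fixture
#'
#' The fixture format is a JSON sidecar (metadata: rate, labels, events,
#' montage, reference; for epochs also the time axis, conditions and flags)
#' pointing at a tab-separated numeric matrix.  Round-trips are lossless to
#' floating-point precision.
#'
#' @param x an [EEGRecording-class] or [EpochSet-class].
#' @param path path of the JSON sidecar to write; the matrix is written next
#'   to it with extension \code{.tsv}.
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(x, path) {
  dataPath <- sub("\\.json$", "", path)
  dataPath <- paste0(dataPath, ".tsv")
  if (is(x, "EEGRecording")) {
    meta <- list(type = "recording", rate = x@rate, labels = x@labels,
                 events = x@events, montage = x@montage,
                 reference = x@reference, data_file = basename(dataPath))
    mat <- x@data
  } else if (is(x, "EpochSet")) {
    d <- dim(x@data)
    meta <- list(type = "epochs", rate = x@rate, labels = x@labels,
                 time = x@time, conditions = x@conditions, kept = x@kept,
                 interpolated = x@interpolated,
                 notes = x@notes, dim = d, data_file = basename(dataPath))
    # trials*channels rows (trial-major), samples in columns
    mat <- matrix(aperm(x@data, c(3, 2, 1)), nrow = d[1] * d[2],
                  ncol = d[3], byrow = TRUE)
  } else stop("unsupported object for fixture export")
  ok <- tryCatch({
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    data.table::fwrite(data.table::as.data.table(mat), dataPath, sep = "\t",
                       col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write error: ", conditionMessage(ok))
  invisible(c(path, dataPath))
}

readFixtureRecording <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  dataPath <- file.path(dirname(path), meta$data_file)
  mat <- as.matrix(data.table::fread(dataPath, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  if (identical(meta$type, "epochs")) stop("fixture holds epochs, not a recording")
  labels <- as.character(meta$labels)
  if (nrow(mat) != length(labels))
    stop("montage/label error: sidecar lists ", length(labels),
         " labels but matrix has ", nrow(mat), " rows")
  events <- if (length(meta$events)) as.data.frame(meta$events) else NULL
  montage <- if (length(meta$montage) && length(meta$montage$label))
    as.data.frame(meta$montage) else NULL
  newRecording(mat, rate = meta$rate, labels = labels, montage = montage,
               events = events,
               reference = if (is.null(meta$reference)) "unknown" else meta$reference)
}

#' Read an EpochSet fixture written by [writeFixture()]
#' @param path path to the JSON sidecar.
#' @return an [EpochSet-class].
#' @export
readFixtureEpochs <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(meta$type, "epochs")) stop("fixture does not hold epochs")
  dataPath <- file.path(dirname(path), meta$data_file)
  mat <- as.matrix(data.table::fread(dataPath, sep = "\t", header = FALSE))
  d <- as.integer(meta$dim)
  arr <- aperm(array(t(mat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  interp <- meta$interpolated
  if (is.null(interp)) interp <- rep(list(character(0)), d[1])
  interp <- lapply(interp, as.character)
  new("EpochSet", data = arr, time = as.numeric(meta$time),
      labels = as.character(meta$labels), rate = meta$rate,
      conditions = as.character(meta$conditions), kept = as.logical(meta$kept),
      interpolated = interp,
      notes = if (length(meta$notes)) as.character(meta$notes) else character(0))
}

# ---- stage outputs --------------------------------------------------------

#' Write intermediate or final stage outputs
#'
#' For an [EpochSet-class] in \code{txt} format, writes (1) the trial-average
#' per channel per timepoint and (2) the per-trial per-channel matrix, as
#' tab-separated tables with channel-name row headers and millisecond column
#' headers.  In \code{fixture} format any object is written losslessly via
#' [writeFixture()].
#'
#' @param object an [EEGRecording-class] or [EpochSet-class].
#' @param stage short stage name used in file names.
#' @param out_dir output directory (created if needed).
#' @param formats character subset of \code{c("txt", "fixture")}.
#' @return character vector of file paths written.
#' @export
writeStageOutputs <- function(object, stage, out_dir,
                              formats = c("txt", "fixture")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("write error: output directory not writable: ", out_dir)
  paths <- character(0)
  if ("fixture" %in% formats) {
    p <- file.path(out_dir, paste0(stage, ".json"))
    writeFixture(object, p)
    paths <- c(paths, p)
  }
  if ("txt" %in% formats && is(object, "EpochSet")) {
    d <- dim(object@data)
    keep <- which(object@kept)
    avg <- if (length(keep))
      apply(object@data[keep, , , drop = FALSE], c(2, 3), mean)
    else matrix(NA_real_, d[2], d[3])
    dimnames(avg) <- list(object@labels, formatC(object@time, format = "g"))
    pAvg <- file.path(out_dir, paste0(stage, "_average.txt"))
    utils::write.table(avg, pAvg, sep = "\t", quote = FALSE, col.names = NA)
    trials <- matrix(aperm(object@data, c(3, 2, 1)), nrow = d[1] * d[2],
                     ncol = d[3], byrow = TRUE)
    rownames(trials) <- paste0("trial", rep(seq_len(d[1]), each = d[2]), "_",
                               rep(object@labels, d[1]))
    colnames(trials) <- formatC(object@time, format = "g")
    pTr <- file.path(out_dir, paste0(stage, "_trials.txt"))
    utils::write.table(trials, pTr, sep = "\t", quote = FALSE, col.names = NA)
    paths <- c(paths, pAvg, pTr)
  }
  paths
}
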