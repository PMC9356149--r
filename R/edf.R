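# Minimal EDF/EDF+ support.  EDF stores 16-bit samples in fixed-duration data
# records with an ASCII header (256 bytes + 256 per signal); EDF+ adds an
# "EDF Annotations" signal carrying time-stamped annotation lists (TALs) that
# we map to event markers.  Only equal-rate ordinary signals are supported.

readAscii <- function(con, n) {
  raw <- readBin(con, "raw", n)
  trimws(rawToChar(raw))
}

#' Read an EDF/EDF+ file
#'
#' Ordinary signals become channels (converted to physical units, assumed
#' microvolts); an \code{EDF Annotations} signal, if present, is parsed into
#' event markers with onsets converted to 0-based sample indices.
#'
#' @param path file path.
#' @return an [EEGRecording-class].
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- tryCatch({
    version <- readAscii(con, 8)
    readAscii(con, 80); readAscii(con, 80)   # patient, recording id
    readAscii(con, 8); readAscii(con, 8)     # date, time
    nbytes <- as.integer(readAscii(con, 8))
    readAscii(con, 44)
    nrec <- as.integer(readAscii(con, 8))
    recdur <- as.numeric(readAscii(con, 8))
    ns <- as.integer(readAscii(con, 4))
    if (is.na(ns) || ns < 1) stop("bad signal count")
    list(nrec = nrec, recdur = recdur, ns = ns)
  }, error = function(e) stop("format error: not a readable EDF file"))
  ns <- hdr$ns
  labels   <- vapply(seq_len(ns), function(i) readAscii(con, 16), "")
  for (i in seq_len(ns)) readAscii(con, 80)            # transducer
  for (i in seq_len(ns)) readAscii(con, 8)             # physical dimension
  physmin  <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  physmax  <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  digmin   <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  digmax   <- vapply(seq_len(ns), function(i) as.numeric(readAscii(con, 8)), 0)
  for (i in seq_len(ns)) readAscii(con, 80)            # prefiltering
  nsamp    <- vapply(seq_len(ns), function(i) as.integer(readAscii(con, 8)), 0L)
  for (i in seq_len(ns)) readAscii(con, 32)            # reserved

  isAnnot <- labels == "EDF Annotations"
  sig <- which(!isAnnot)
  if (!length(sig)) stop("format error: no ordinary signals in EDF file")
  rate <- nsamp[sig] / hdr$recdur
  if (max(abs(rate - rate[1])) > 1e-9)
    stop("format error: signals with differing sampling rates are not supported")
  rate <- rate[1]

  nrec <- hdr$nrec
  chunks <- vector("list", nrec)
  annotRaw <- list()
  for (r in seq_len(nrec)) {
    recdata <- vector("list", ns)
    for (i in seq_len(ns)) {
      if (isAnnot[i]) {
        annotRaw[[length(annotRaw) + 1L]] <- readBin(con, "raw", 2L * nsamp[i])
        recdata[[i]] <- NULL
      } else {
        recdata[[i]] <- readBin(con, "integer", nsamp[i], size = 2L,
                                signed = TRUE, endian = "little")
      }
    }
    chunks[[r]] <- do.call(rbind, lapply(sig, function(i) {
      scale <- (physmax[i] - physmin[i]) / (digmax[i] - digmin[i])
      (recdata[[i]] - digmin[i]) * scale + physmin[i]
    }))
  }
  data <- do.call(cbind, chunks)
  events <- parseEdfAnnotations(annotRaw, rate)
  rec <- newRecording(data, rate = rate, labels = labels[sig], events = events)
  addProvenance(rec, "load", list(format = "edf", path = path))
}

parseEdfAnnotations <- function(rawChunks, rate) {
  if (!length(rawChunks)) return(NULL)
  bytes <- do.call(c, rawChunks)
  # TALs are NUL-terminated; split on zero bytes at the raw level
  zero <- bytes == as.raw(0)
  grp <- cumsum(c(TRUE, zero[-length(zero)]))
  tals <- vapply(split(bytes[!zero], grp[!zero]), rawToChar, "")
  out <- list()
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next                      # record timestamp TAL
    onsetS <- as.numeric(sub("\x15.*$", "", parts[1]))
    anns <- parts[-1]
    anns <- anns[nzchar(anns)]
    for (a in anns)
      out[[length(out) + 1L]] <- data.frame(name = a,
                                            onset = round(onsetS * rate))
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

padAscii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEGRecording as EDF/EDF+
#'
#' Writes a single data record holding the whole signal (16-bit physical
#' scaling per channel) plus, when events are present, an
#' \code{EDF Annotations} signal with one TAL per event.  Intended for
#' exchanging synthetic or processed data; amplitudes are quantized to the
#' 16-bit EDF grid.
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEdf <- function(rec, path) {
  data <- rec@data
  nchan <- nrow(data)
  nsamp <- ncol(data)
  recdur <- nsamp / rec@rate
  events <- rec@events
  hasAnnot <- nrow(events) > 0
  ns <- nchan + as.integer(hasAnnot)

  physmin <- apply(data, 1, min)
  physmax <- apply(data, 1, max)
  flat <- physmax - physmin < 1e-12
  physmax[flat] <- physmin[flat] + 1
  digmin <- -32768; digmax <- 32767
  dig <- round((data - physmin) / (physmax - physmin) * (digmax - digmin) + digmin)

  annot <- raw(0)
  if (hasAnnot) {
    tals <- c(sprintf("+0\x14\x14"),
              sprintf("+%.7g\x14%s\x14", events$onset / rec@rate, events$name))
    annot <- do.call(c, lapply(tals, function(t) c(charToRaw(t), as.raw(0))))
    if (length(annot) %% 2 == 1) annot <- c(annot, as.raw(0))
  }
  annotSamp <- length(annot) / 2

  con <- file(path, "wb")
  on.exit(close(con))
  wa <- function(x, w) writeChar(padAscii(x, w), con, nchars = w, eos = NULL)
  wa("0", 8); wa("anonymous", 80); wa("erpflow export", 80)
  wa("01.01.26", 8); wa("00.00.00", 8)
  wa(256 * (ns + 1), 8)
  wa(if (hasAnnot) "EDF+C" else "", 44)
  wa(1, 8)                                  # one data record
  wa(format(recdur, digits = 7), 8)
  wa(ns, 4)
  allLab <- c(rec@labels, if (hasAnnot) "EDF Annotations")
  for (l in allLab) wa(l, 16)
  for (i in seq_len(ns)) wa("", 80)
  for (i in seq_len(ns)) wa(if (i <= nchan) "uV" else "", 8)
  for (i in seq_len(ns)) wa(format(if (i <= nchan) physmin[i] else -1, digits = 7), 8)
  for (i in seq_len(ns)) wa(format(if (i <= nchan) physmax[i] else 1, digits = 7), 8)
  for (i in seq_len(ns)) wa(digmin, 8)
  for (i in seq_len(ns)) wa(digmax, 8)
  for (i in seq_len(ns)) wa("", 80)
  for (i in seq_len(ns)) wa(if (i <= nchan) nsamp else annotSamp, 8)
  for (i in seq_len(ns)) wa("", 32)
  for (i in seq_len(nchan))
    writeBin(as.integer(dig[i, ]), con, size = 2L, endian = "little")
  if (hasAnnot) writeBin(annot, con)
  invisible(path)
}
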