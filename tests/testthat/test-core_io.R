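test_that("fixture round trip preserves data, labels, events and montage", {
  ev <- data.frame(name = c("a", "b"), onset = c(100, 600),
                   condition = c("x", NA))
  rec <- makeTestRecording(4, 1000, 250, seed = 2, montage = TRUE,
                           events = ev)
  path <- file.path(withr::local_tempdir(), "rec.json")
  writeFixture(rec, path)
  rec2 <- readRecording(path, "fixture")
  relErr <- max(abs(eegData(rec2) - eegData(rec))) /
    max(abs(eegData(rec)))
  expect_lt(relErr, 1e-9)
  expect_identical(channelLabels(rec2), channelLabels(rec))
  expect_equal(eventTable(rec2)$name, eventTable(rec)$name)
  expect_equal(eventTable(rec2)$onset, eventTable(rec)$onset)
  expect_equal(samplingRate(rec2), 250)
  expect_equal(channelMontage(rec2)$z, channelMontage(rec)$z,
               tolerance = 1e-12)
})

test_that("fixture with label/matrix mismatch raises a montage error", {
  rec <- makeTestRecording(4, 200, 250)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.json")
  writeFixture(rec, path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta$labels <- c(meta$labels, "E5")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  expect_error(readRecording(path, "fixture"), "montage/label")
})

test_that("EDF round trip preserves signal within 16-bit quantization", {
  ev <- data.frame(name = "stm+", onset = 500)
  rec <- makeTestRecording(4, 1000, 500, seed = 3, events = ev)
  path <- file.path(withr::local_tempdir(), "t.edf")
  writeEdf(rec, path)
  rec2 <- readRecording(path, "edf")
  rng <- diff(range(eegData(rec)))
  expect_lt(max(abs(eegData(rec2) - eegData(rec))), rng / 65535)
  expect_identical(channelLabels(rec2), channelLabels(rec))
  expect_equal(samplingRate(rec2), 500)
  # annotation at 1.0 s -> onset sample 500 at 500 Hz
  expect_equal(eventTable(rec2)$onset, 500)
  expect_equal(eventTable(rec2)$name, "stm+")
})

test_that("hand-built EDF bytes are parsed per the published layout", {
  # one signal, one 1-s record of 4 samples at digital==physical scaling
  path <- file.path(withr::local_tempdir(), "hand.edf")
  con <- file(path, "wb")
  wa <- function(x, w) writeChar(formatC(substr(as.character(x), 1, w),
                                         width = w, flag = "-"),
                                 con, nchars = w, eos = NULL)
  wa("0", 8); wa("p", 80); wa("r", 80); wa("01.01.20", 8); wa("00.00.00", 8)
  wa(512, 8); wa("", 44); wa(1, 8); wa(1, 8); wa(1, 4)
  wa("C3", 16); wa("", 80); wa("uV", 8)
  wa(-32768, 8); wa(32767, 8); wa(-32768, 8); wa(32767, 8)
  wa("", 80); wa(4, 8); wa("", 32)
  writeBin(c(0L, 100L, -100L, 32767L), con, size = 2L, endian = "little")
  close(con)
  rec <- readEdf(path)
  expect_identical(channelLabels(rec), "C3")
  expect_equal(samplingRate(rec), 4)
  expect_equal(as.numeric(eegData(rec)), c(0, 100, -100, 32767))
})

test_that("channel selection honours include/exclude and forgets channels", {
  rec <- makeTestRecording(8, 500, 250)
  inc <- selectChannels(rec, "include", c("E2", "E5", "E7"))
  expect_identical(channelLabels(inc), c("E2", "E5", "E7"))
  exc <- selectChannels(rec, "exclude", c("E1", "E8"))
  expect_identical(channelLabels(exc), paste0("E", 2:7))
  expect_equal(nChannels(selectChannels(rec, "all")), 8)
  expect_error(selectChannels(rec, "include", "nope"), "selection error")
  # removed channels are gone downstream
  expect_error(selectChannels(inc, "include", "E1"), "selection error")
})

test_that("resampling preserves amplitude, duration and event positions", {
  n <- 8000
  x <- 10 * sin(2 * pi * 10 * (0:(n - 1)) / 1000)
  rec <- newRecording(matrix(x, 1), 1000,
                      events = data.frame(name = "a", onset = c(1000, 5000)))
  r2 <- resampleRecording(rec, 250)
  expect_equal(nSamples(r2), 2000)
  y <- eegData(r2)[1, ]
  t <- (seq_along(y) - 1) / 250
  amp <- max(abs(coef(lm(y ~ sin(2 * pi * 10 * t) - 1))))
  expect_lt(abs(amp - 10) / 10, 0.01)
  expect_equal(eventTable(r2)$onset, c(250, 1250))
  # identity and upsample guard
  expect_equal(eegData(resampleRecording(rec, 1000)), eegData(rec))
  expect_error(resampleRecording(r2, 500), "upsample error")
})

test_that("stage outputs write average and per-trial tables of right shape", {
  set.seed(4)
  ep <- makeTestEpochs(array(rnorm(10 * 4 * 100), c(10, 4, 100)))
  dir <- withr::local_tempdir()
  paths <- writeStageOutputs(ep, "final", dir, c("txt", "fixture"))
  avg <- read.table(grep("average", paths, value = TRUE), sep = "\t",
                    header = TRUE, row.names = 1, check.names = FALSE)
  expect_equal(dim(avg), c(4, 100))
  tr <- read.table(grep("trials", paths, value = TRUE), sep = "\t",
                   header = TRUE, row.names = 1, check.names = FALSE)
  expect_equal(dim(tr), c(40, 100))
  # epochs fixture round trip
  ep2 <- readFixtureEpochs(grep("json$", paths, value = TRUE))
  expect_equal(eegData(ep2), eegData(ep), tolerance = 1e-9)
  expect_identical(keptTrials(ep2), keptTrials(ep))
})

test_that("unusable output directory raises a write error", {
  dir <- withr::local_tempdir()
  blocker <- file.path(dir, "blocker")
  writeLines("x", blocker)            # a file where the directory should go
  rec <- makeTestRecording(2, 100, 100)
  expect_error(writeStageOutputs(rec, "s", blocker, "fixture"),
               "write error")
})
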