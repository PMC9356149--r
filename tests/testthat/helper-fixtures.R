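# Shared fixture builders.  All data are generated in code; no files ship
# with the tests.

# deterministic multichannel recording with optional montage and events
makeTestRecording <- function(nch = 4, n = 1000, rate = 250, seed = 1,
                              montage = FALSE, events = NULL) {
  set.seed(seed)
  data <- matrix(rnorm(nch * n), nch, n)
  mont <- if (montage) erpflow:::hemisphereMontage(nch) else NULL
  labels <- if (montage) mont$label else paste0("E", seq_len(nch))
  newRecording(data, rate = rate, labels = labels, montage = mont,
               events = events)
}

# unit-variance pink noise (package-internal generator, reused in tests)
testPink <- function(n, seed) {
  set.seed(seed)
  erpflow:::pinkNoise(n)
}

# epoch set with controlled per-trial values: trials x channels x samples
makeTestEpochs <- function(arr, rate = 250, t0_ms = -100) {
  d <- dim(arr)
  time <- (seq_len(d[3]) - 1) * 1000 / rate + t0_ms
  new("EpochSet", data = arr, time = time,
      labels = paste0("E", seq_len(d[2])), rate = rate,
      conditions = rep("a", d[1]), kept = rep(TRUE, d[1]),
      interpolated = rep(list(character(0)), d[1]), notes = character(0))
}

# simple ERP waveform object
makeWaveform <- function(values, rate = 1000, t0_ms = 0) {
  structure(list(values = values,
                 time = (seq_along(values) - 1) * 1000 / rate + t0_ms,
                 n_trials = 1L, note = NULL),
            class = "ERPWaveform")
}
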