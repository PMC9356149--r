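test_that("coefficient thresholding splits exactly as specified", {
  s <- thresholdCoefficients(5, 3, "soft")
  expect_equal(s$artifact, 2)
  expect_equal(s$retained, 3)
  h <- thresholdCoefficients(5, 3, "hard")
  expect_equal(h$artifact, 5)
  expect_equal(h$retained, 0)
  for (m in c("soft", "hard")) {
    r <- thresholdCoefficients(2, 3, m)
    expect_equal(r$artifact, 0)
    expect_equal(r$retained, 2)
  }
  # vectorized, signs, exact additivity
  w <- c(-7, -3, -0.5, 0, 0.5, 3, 7)
  for (m in c("soft", "hard")) {
    r <- thresholdCoefficients(w, 2.5, m)
    expect_identical(r$artifact + r$retained, w)
  }
  expect_equal(thresholdCoefficients(-7, 2.5, "soft")$artifact, -4.5)
})

test_that("undecimated transform reconstructs perfectly and localizes bands", {
  x <- sin((1:512) / 5) + cos((1:512) / 37)
  dec <- erpflow:::modwt(x, 5)
  expect_lt(max(abs(erpflow:::imodwt(dec) - x)), 1e-10)
  # a 50 Hz tone at 1000 Hz lands in the 31-62 Hz detail level (4)
  tone <- sin(2 * pi * 50 * (0:4095) / 1000)
  d <- erpflow:::modwt(tone, 7)
  sds <- apply(d$W, 2, sd)
  expect_equal(which.max(sds), 4)
})

test_that("cleaned + removed equals the input exactly, all-zero maps to zero", {
  set.seed(21)
  rec <- newRecording(matrix(rnorm(3 * 2000) * 20, 3), 250)
  for (m in c("soft", "hard")) {
    wc <- waveletClean(rec, waveletSettings(mode = m))
    expect_lt(max(abs(eegData(wc$rec) + eegData(wc$removed) -
                        eegData(rec))), 1e-6)
  }
  z <- waveletClean(newRecording(matrix(0, 2, 1000), 250))
  expect_true(all(eegData(z$rec) == 0))
  expect_true(all(eegData(z$removed) == 0))
  expect_error(waveletClean(newRecording(matrix(0, 1, 50), 250)),
               "length error")
})

test_that("hard thresholding removes at least as much as soft, everywhere", {
  # coefficientwise |retained_hard| <= |retained_soft| by construction
  w <- seq(-10, 10, by = 0.01)
  soft <- thresholdCoefficients(w, 2, "soft")
  hard <- thresholdCoefficients(w, 2, "hard")
  expect_true(all(abs(hard$retained) <= abs(soft$retained) + 1e-12))
  # and removed variance ordering holds on signals
  set.seed(22)
  for (s in 1:3) {
    x <- 20 * testPink(3000, 500 + s)
    x[1000:1050] <- x[1000:1050] + 300
    rec <- newRecording(matrix(x, 1), 250)
    vS <- var(as.numeric(eegData(waveletClean(rec,
      waveletSettings(mode = "soft"))$removed)))
    vH <- var(as.numeric(eegData(waveletClean(rec,
      waveletSettings(mode = "hard"))$removed)))
    expect_gte(vH, vS)
  }
})

test_that("a large square-pulse artifact is suppressed, far samples spared", {
  sim <- synthesizeEpochs()
  clean <- eegData(sim$train)[1, ]
  pulse <- 10001:10100
  runHard <- function(v)
    eegData(waveletClean(newRecording(matrix(v, 1), 1000),
                         waveletSettings(mode = "hard"))$rec)[1, ]
  # noise-free train + 500 uV, 100 ms square pulse: peak reduced > 80 %
  withPulse <- clean
  withPulse[pulse] <- withPulse[pulse] + 500
  expect_lt(max(runHard(withPulse)[pulse] - clean[pulse]), 0.2 * 500)
  # time-locality on EEG-scale background: the pulse's effect on the
  # correction, isolated by differencing against the pulse-free cleaning,
  # falls below 1 uV RMS beyond 1 s (the coarsest undecimated detail
  # filters span seconds, so perturbations cannot vanish within 200 ms)
  x <- clean + 20 * testPink(30000, 61)
  x2 <- x
  x2[pulse] <- x2[pulse] + 500
  y <- runHard(x)
  y2 <- runHard(x2)
  far <- c(1:9000, 11101:30000)
  expect_lt(sqrt(mean((y2[far] - y[far])^2)), 1)
})

test_that("realistic-background cleaning preserves the embedded ERP", {
  # On data with EEG-scale background the universal threshold sits far above
  # the ERP's coefficients, so correction leaves the evoked signal intact.
  sim <- synthesizeEpochs()
  x <- eegData(sim$train)[1, ]
  bg <- 20 * testPink(length(x), 62)
  rec <- newRecording(matrix(x + bg, 1), 1000,
                      events = eventTable(sim$train))
  wc <- waveletClean(rec, waveletSettings(mode = "soft"))
  expect_gt(cor(x + bg, eegData(wc$rec)[1, ]), 0.98)
  ep <- baselineCorrect(segmentEvents(wc$rec, "vep",
                                      segmentationSettings()), c(-100, 0))
  epRaw <- baselineCorrect(segmentEvents(rec, "vep",
                                         segmentationSettings()), c(-100, 0))
  n1 <- findPeaks(averageTrials(ep), vepMeasureWindows(-100))$windows$peak[1]
  n1Raw <- findPeaks(averageTrials(epRaw),
                     vepMeasureWindows(-100))$windows$peak[1]
  expect_lt(abs(n1 - n1Raw) / abs(n1Raw), 0.05)
})
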