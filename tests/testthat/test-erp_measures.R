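test_that("trial and channel averaging respects kept flags and exclusions", {
  arr <- array(0, c(2, 2, 10))
  arr[1, , ] <- 1
  arr[2, , ] <- 3
  ep <- makeTestEpochs(arr)
  w <- averageTrials(ep)
  expect_equal(w$values, rep(2, 10))
  expect_equal(w$n_trials, 2L)
  # a bad channel valued 1e6 is excluded from the average
  arr2 <- arr
  arr2[, 2, ] <- 1e6
  ep2 <- makeTestEpochs(arr2)
  w2 <- averageTrials(ep2, exclude = "E2")
  expect_equal(w2$values, rep(2, 10))
  # single kept trial is identity
  ep@kept <- c(TRUE, FALSE)
  expect_equal(averageTrials(ep)$values, rep(1, 10))
  ep@kept <- c(FALSE, FALSE)
  expect_equal(averageTrials(ep)$n_trials, 0L)
})

test_that("grand average computes SE and the 95% confidence band", {
  w1 <- makeWaveform(rep(1, 20))
  w3 <- makeWaveform(rep(3, 20))
  g <- grandAverage(list(w1, w3))
  expect_equal(g$mean, rep(2, 20))
  expect_equal(g$se, rep(1, 20))           # sd = sqrt(2), /sqrt(2)
  expect_equal(g$ci_high - g$mean, 1.96 * g$se)
  # identical inputs: SE identically zero
  g0 <- grandAverage(list(w1, w1, w1))
  expect_true(all(g0$se == 0))
  expect_error(grandAverage(list(w1, makeWaveform(rep(1, 10)))),
               "alignment error")
})

test_that("windowed peaks, global extrema and tie-breaking follow the rules", {
  tri <- c(seq(0, 5, length.out = 101), seq(5, 0, length.out = 100)[-1])
  w <- makeWaveform(tri)                     # peaks 5 uV at 100 ms
  pk <- findPeaks(w, list(measureWindow(50, 150, "max", "tri")))
  expect_equal(pk$windows$peak, 5)
  expect_equal(pk$windows$latency, 100)
  expect_equal(pk$global$peak[1], 5)
  # plateau of equal maxima: earliest latency reported
  flat <- c(0, 1, 3, 3, 3, 1, 0)
  pf <- findPeaks(makeWaveform(flat),
                  list(measureWindow(0, 6, "max")))
  expect_equal(pf$windows$latency, 2)
  expect_error(findPeaks(w, list(measureWindow(900, 999, "max"))),
               "window error")
})

test_that("zero-crossing windows partition the post-stimulus axis", {
  v <- sin(2 * pi * (0:999) / 1000)          # one full period
  v[abs(v) < 1e-12] <- 0                     # land the half-period on zero
  zw <- zeroCrossingWindows(makeWaveform(v))
  expect_equal(nrow(zw), 2)
  expect_equal(zw$start_ms[2], 500)          # exact zero is a boundary
  # exact zero sample becomes a boundary
  v2 <- c(1, 1, 0, -1, -1)
  zw2 <- zeroCrossingWindows(makeWaveform(v2))
  expect_true(2 %in% zw2$start_ms)
  # strictly positive waveform: one window spanning the range
  zw3 <- zeroCrossingWindows(makeWaveform(rep(2, 50)))
  expect_equal(nrow(zw3), 1)
  expect_equal(zw3$end_ms, 49)
  # windows tile the axis without gaps
  set.seed(20)
  v4 <- rnorm(200)
  zw4 <- zeroCrossingWindows(makeWaveform(v4))
  expect_equal(zw4$start_ms[1], 0)
  expect_equal(zw4$end_ms[nrow(zw4)], 199)
  expect_equal(zw4$start_ms[-1], zw4$end_ms[-nrow(zw4)])
})

test_that("mean amplitude matches closed forms", {
  expect_equal(meanAmplitude(makeWaveform(rep(4.5, 100)), c(10, 50)), 4.5)
  ramp <- seq(0, 10, length.out = 101)
  expect_equal(meanAmplitude(makeWaveform(ramp), c(0, 100)), 5,
               tolerance = 0.02)
  halfSine <- 3 * sin(pi * (0:200) / 200)
  expect_equal(meanAmplitude(makeWaveform(halfSine), c(0, 200)),
               2 * 3 / pi, tolerance = 0.02)
  expect_error(meanAmplitude(makeWaveform(ramp), c(500, 600)),
               "window error")
})

test_that("area measures match closed forms and definitions", {
  # rectangle: a uV for d ms
  rect <- makeWaveform(c(rep(0, 10), rep(2, 101), rep(0, 10)))
  am <- areaMeasures(rect, c(10, 110))
  expect_equal(am$auc, 200, tolerance = 0.01)
  expect_equal(am$auc50_latency, 60, tolerance = 1)
  # half sine amplitude A duration T: AUC = 2AT/pi
  A <- 4; T <- 300
  hs <- makeWaveform(A * sin(pi * (0:T) / T))
  expect_equal(areaMeasures(hs, c(0, T))$auc, 2 * A * T / pi,
               tolerance = 0.01 * 2 * A * T / pi)
  # full sine: signed AUC ~ 0, global absolute AUC = 4A T_period / (2 pi)
  fs <- makeWaveform(A * sin(2 * pi * (0:999) / 1000))
  expect_lt(abs(areaMeasures(fs, c(0, 999))$auc), 1)
  expect_equal(areaMeasures(fs)$global_abs_auc, 4 * A * 1000 / (2 * pi),
               tolerance = 0.01 * 4 * A * 1000 / (2 * pi))
  # zero waveform: sentinel latency
  expect_true(is.na(areaMeasures(makeWaveform(rep(0, 50)))$auc50_latency))
})

test_that("AUC is additive over a partition and latency shifts covariantly", {
  set.seed(21)
  v <- rnorm(300)
  w <- makeWaveform(v)
  zw <- zeroCrossingWindows(w)
  parts <- vapply(seq_len(nrow(zw)), function(i)
    areaMeasures(w, c(zw$start_ms[i], zw$end_ms[i]))$auc, 0)
  expect_equal(sum(parts), areaMeasures(w, c(0, 299))$auc, tolerance = 1e-9)
  # shifting the waveform later shifts the AUC50 latency by the same amount
  v2 <- abs(rnorm(100)) + 0.5
  lat1 <- areaMeasures(makeWaveform(v2), c(0, 99))$auc50_latency
  lat2 <- areaMeasures(makeWaveform(c(rep(0, 40), v2)),
                       c(40, 139))$auc50_latency
  expect_equal(lat2, lat1 + 40)
})

test_that("peak-to-peak uses current minus prior and matches the benchmark", {
  pp <- peakToPeak(c(N1 = -7.42, P1 = 8.61))
  expect_equal(unname(pp), 16.03)
  expect_identical(names(pp), "N1-P1")
  expect_equal(unname(peakToPeak(c(a = 5, b = 5))), 0)
  # the source-free component sum gives P1 = 6.38: N1 -> P1 span 13.80
  expect_equal(unname(peakToPeak(c(-7.42, 6.38))), 13.80)
})

test_that("measures are linear under waveform scaling where defined", {
  set.seed(22)
  v <- rnorm(200) + 1
  w1 <- makeWaveform(v)
  w2 <- makeWaveform(3 * v)
  expect_equal(meanAmplitude(w2, c(10, 150)),
               3 * meanAmplitude(w1, c(10, 150)))
  expect_equal(areaMeasures(w2, c(10, 150))$auc,
               3 * areaMeasures(w1, c(10, 150))$auc)
})
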