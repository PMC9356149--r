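test_that("single-component waveforms hit their tabulated extrema", {
  n1 <- componentWaveform(componentSpec(170, 60, -7.5), 1000, 500)
  expect_equal(min(n1), -7.5)
  expect_equal(which.min(n1), 171)              # 170 ms at 1000 Hz, 0-based
  p1 <- componentWaveform(componentSpec(200, 60, 7.5), 1000, 500)
  expect_equal(max(p1), 7.5)
  n2 <- componentWaveform(componentSpec(235, 100, -10), 1000, 500)
  expect_equal(min(n2), -10)
  expect_true(all(componentWaveform(componentSpec(200, 60, 0), 1000, 500)
                  == 0))
  # value at center +/- width/2 equals amplitude * exp(-4.5) (sigma rule)
  expect_equal(n1[171 + 30] / -7.5, exp(-4.5), tolerance = 1e-9)
  expect_equal(n1[171 - 30] / -7.5, exp(-4.5), tolerance = 1e-9)
})

test_that("the default train has the documented geometry and markers", {
  sim <- synthesizeEpochs()
  expect_equal(nTrials(sim$epochs), 60)
  expect_equal(nSamples(sim$train) / samplingRate(sim$train), 30)
  ev <- eventTable(sim$train)
  expect_equal(nrow(ev), 60)
  expect_equal(ev$onset[1], 100)               # marker 100 ms into epoch 1
  expect_equal(diff(ev$onset), rep(500, 59))
  # slope rule: last-epoch N1 amplitude is A + slope = -9.5
  lastEp <- eegData(sim$epochs)[60, 1, ]
  n1Only <- synthesizeEpochs(list(componentSpec(170, 60, -7.5, -2)))
  expect_equal(min(eegData(n1Only$epochs)[60, 1, ]), -9.5)
  expect_equal(min(eegData(n1Only$epochs)[1, 1, ]), -7.5)
  # component spilling out of the epoch is rejected
  expect_error(synthesizeEpochs(list(componentSpec(490, 60, 5))),
               "spec error")
})

test_that("the summed first-epoch waveform reproduces the printed N1", {
  sim <- synthesizeEpochs()
  ep1 <- eegData(sim$epochs)[1, 1, ]
  t <- (seq_along(ep1) - 1)                    # ms at 1000 Hz, epoch axis
  win <- t >= 150 & t <= 190
  expect_equal(min(ep1[win]), -7.420, tolerance = 0.5 / 100 * 7.42)
  # P1 window max of the source-free sum is ~6.38 uV
  expect_equal(max(ep1[t >= 180 & t <= 220]), 6.38, tolerance = 0.01)
})

test_that("embedding tiles, trims and adds exactly", {
  sim <- synthesizeEpochs(settings = simSettings(rate = 250))
  base <- makeBaselineEeg(6, 125, 250, seed = 30)
  emb <- embedInBaseline(sim$train, base)
  expect_equal(nSamples(emb) / 250, 120)        # 5 s trimmed
  expect_equal(nrow(eventTable(emb)), 240)
  # embedded minus baseline equals the tiled train on every channel
  tiled <- rep(eegData(sim$train)[1, ], 4)
  diffs <- eegData(emb) - eegData(base)[, 1:(120 * 250)]
  for (ch in 1:6) expect_equal(unname(diffs[ch, ]), tiled)
  # exactly one tile fits a train-length baseline
  base30 <- makeBaselineEeg(3, 30, 250, seed = 31)
  emb30 <- embedInBaseline(sim$train, base30)
  expect_equal(nSamples(emb30), nSamples(sim$train))
  expect_error(embedInBaseline(sim$train,
                               makeBaselineEeg(3, 10, 250, seed = 32)),
               "length error")
})

test_that("artifact injection is seeded, additive and class-faithful", {
  rec <- makeBaselineEeg(8, 20, 250, seed = 33)
  specs <- list(artifactSpec("blink", 200, 10),
                artifactSpec("emg", 30, 12),
                artifactSpec("drift", 25),
                artifactSpec("line", 10))
  a1 <- injectArtifacts(rec, specs, seed = 5)
  a2 <- injectArtifacts(rec, specs, seed = 5)
  expect_identical(eegData(a1$rec), eegData(a2$rec))
  expect_equal(eegData(a1$rec) - eegData(rec), eegData(a1$artifact),
               ignore_attr = TRUE)
  # zero amplitudes: identity
  z <- injectArtifacts(rec, list(artifactSpec("blink", 0)), seed = 5)
  expect_identical(eegData(z$rec), eegData(rec))
  # line artifact concentrates at 60 Hz
  lineOnly <- injectArtifacts(rec, list(artifactSpec("line", 10)), seed = 6)
  art <- eegData(lineOnly$artifact)[1, ]
  sp <- Mod(fft(art))^2
  fr <- (0:(length(art) - 1)) * 250 / length(art)
  expect_gt(sum(sp[abs(fr - 60) < 1]) / sum(sp[fr <= 125]), 0.99)
  # blinks are frontally weighted (montage y > 0 channels carry more)
  blinks <- injectArtifacts(rec, list(artifactSpec("blink", 200, 20)),
                            seed = 7)
  pw <- apply(eegData(blinks$artifact), 1, var)
  frontal <- channelMontage(rec)$y > 0.5
  expect_gt(mean(pw[frontal]), mean(pw[!frontal]))
})

test_that("evaluation report computes rejection, distortion and retention", {
  sim <- synthesizeEpochs(settings = simSettings(rate = 250))
  truth <- averageTrials(sim$epochs)
  wins <- vepMeasureWindows(-100)
  # processed == ground truth: zero distortion, zero SE, full retention
  processed <- replicate(4, sim$epochs, simplify = FALSE)
  rep0 <- evaluatePipeline(processed, truth, simSettings(rate = 250), wins)
  expect_equal(rep0$participant_rejection_rate, 0)
  expect_equal(unname(rep0$distortion_uv), rep(0, 3))
  expect_equal(unname(rep0$se), rep(0, 3))
  expect_equal(rep0$retention_pct, 100)
  # identical clean and artifact sets: zero difference
  repSame <- evaluatePipeline(processed, truth, simSettings(rate = 250),
                              wins, processedArtifact = processed)
  expect_equal(repSame$clean_vs_artifact_uv, 0)
  # one of four files fully rejected -> 25 %
  dead <- sim$epochs
  dead@kept[] <- FALSE
  rep1 <- evaluatePipeline(c(processed[1:3], list(dead)), truth,
                           simSettings(rate = 250), wins)
  expect_equal(rep1$participant_rejection_rate, 25)
  expect_equal(rep1$segments_retained, 180)
  expect_equal(rep1$segments_total, 240)
})

test_that("sim outputs are deterministic under a fixed seed", {
  b1 <- makeBaselineEeg(5, 10, 250, seed = 42)
  b2 <- makeBaselineEeg(5, 10, 250, seed = 42)
  expect_identical(eegData(b1), eegData(b2))
  b3 <- makeBaselineEeg(5, 10, 250, seed = 43)
  expect_false(identical(eegData(b1), eegData(b3)))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(makeBaselineEeg(3, 5, 250, seed = 1))
  after <- rnorm(3)
  expect_identical(before, after)
})
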