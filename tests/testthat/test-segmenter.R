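test_that("segmentation arithmetic, offsets and bounds behave as specified", {
  rate <- 1000
  n <- 3000
  data <- matrix(seq_len(2 * n), 2, n, byrow = TRUE)
  ev <- data.frame(name = "s", onset = c(1000, 1500))
  rec <- newRecording(data, rate, events = ev)
  ep <- segmentEvents(rec, "s", segmentationSettings(window = c(-100, 400)))
  expect_equal(nTrials(ep), 2)
  expect_equal(nSamples(ep), 500)
  # half-open ranges [900, 1400) and [1400, 1900): first sample values
  expect_equal(eegData(ep)[1, 1, 1], data[1, 901])
  expect_equal(eegData(ep)[2, 1, 1], data[1, 1401])
  expect_equal(epochTime(ep)[1], -100)
  # a 16 ms timing offset shifts both ranges by +16 samples at 1000 Hz
  ep16 <- segmentEvents(rec, "s",
                        segmentationSettings(window = c(-100, 400),
                                             timing_offset_ms = 16))
  expect_equal(eegData(ep16)[1, 1, 1], data[1, 917])
  # event too close to the edge is dropped and counted
  ev2 <- rbind(ev, data.frame(name = "s", onset = 50))
  rec2 <- newRecording(data, rate, events = ev2)
  ep2 <- segmentEvents(rec2, "s", segmentationSettings(window = c(-100, 400)))
  expect_equal(nTrials(ep2), 2)
  expect_match(paste(ep2@notes, collapse = " "), "1 event")
  # zero matching events: empty set with notation, not an exception
  ep0 <- segmentEvents(rec, "absent", segmentationSettings())
  expect_equal(nTrials(ep0), 0)
  expect_match(paste(ep0@notes, collapse = " "), "no trials")
})

test_that("baseline correction subtracts the pre-stimulus mean exactly", {
  arr <- array(7, c(3, 2, 100))
  ep <- makeTestEpochs(arr, rate = 250, t0_ms = -100)
  out <- baselineCorrect(ep, c(-100, 0))
  expect_true(all(eegData(out) == 0))
  # 2 during baseline, 9 after -> post-stimulus becomes 7
  arr2 <- array(2, c(1, 1, 100))
  arr2[, , 27:100] <- 9                      # time >= 4 ms
  ep2 <- makeTestEpochs(arr2, rate = 250, t0_ms = -100)
  out2 <- baselineCorrect(ep2, c(-100, 0))
  expect_equal(eegData(out2)[1, 1, 60], 7)
  # random input: post-correction baseline mean is zero
  set.seed(13)
  ep3 <- makeTestEpochs(array(rnorm(600), c(3, 2, 100)))
  out3 <- baselineCorrect(ep3, c(-100, 0))
  sel <- epochTime(out3) <= 0
  bl <- apply(eegData(out3)[, , sel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  expect_error(baselineCorrect(ep3, c(-300, -200)), "window error")
})

test_that("per-segment channel statistics flag planted outliers", {
  set.seed(14)
  arr <- array(rnorm(30 * 4 * 100), c(30, 4, 100))
  base <- fasterEpochChannelFlags(makeTestEpochs(arr))
  expect_false(any(base[, 2][-5]))
  arr5 <- arr
  arr5[5, 2, ] <- arr5[5, 2, ] * 5
  flags <- fasterEpochChannelFlags(makeTestEpochs(arr5))
  expect_true(flags[5, 2])
  # spike flagged through the amplitude-range metric
  arr6 <- arr
  arr6[7, 3, 50] <- arr6[7, 3, 50] + 300
  flags6 <- fasterEpochChannelFlags(makeTestEpochs(arr6),
    fasterSettings(metrics = "amplitude_range"))
  expect_true(flags6[7, 3])
  expect_false(any(flags6[-7, 3]))
  # identical trials: zero-SD guard, nothing flagged
  same <- array(rep(arr[1, , ], each = 30), c(30, 4, 100))
  expect_false(any(fasterEpochChannelFlags(makeTestEpochs(same))))
})

test_that("within-segment interpolation reconstructs smooth fields", {
  mont <- erpflow:::hemisphereMontage(32)
  nt <- 4
  arr <- array(0, c(nt, 32, 50))
  for (tr in seq_len(nt))
    arr[tr, , ] <- outer(mont$z, rep(1, 50)) * tr   # first-degree harmonic
  ep <- makeTestEpochs(arr)
  ep@labels <- mont$label
  flags <- matrix(FALSE, nt, 32)
  flags[2, 5] <- TRUE
  out <- interpolateWithinSegments(ep, flags, mont)
  err <- sqrt(mean((eegData(out)[2, 5, ] - arr[2, 5, ])^2)) /
    sd(mont$z * 2)
  expect_lt(err, 0.05)
  expect_identical(out@interpolated[[2]], mont$label[5])
  # no flags: identity
  out0 <- interpolateWithinSegments(ep, matrix(FALSE, nt, 32), mont)
  expect_identical(eegData(out0), eegData(ep))
  # constant field: interpolated value equals the constant
  arrC <- array(4.2, c(nt, 32, 50))
  epC <- makeTestEpochs(arrC)
  epC@labels <- mont$label
  outC <- interpolateWithinSegments(epC, flags, mont)
  expect_equal(eegData(outC)[2, 5, ], rep(4.2, 50), tolerance = 1e-6)
})

test_that("amplitude rejection marks threshold crossings, ROI restricts it", {
  arr <- array(0, c(5, 3, 60))
  arr[2, 1, 10] <- 151                      # +151 uV crossing on E1
  arr[4, 3, 20] <- -151
  ep <- makeTestEpochs(arr)
  res <- rejectSegments(ep, rejectionPolicy("amplitude", -150, 150))
  expect_identical(which(!keptTrials(res$epochs)), c(2L, 4L))
  # ROI excluding the artifact channel retains the trial
  roi <- rejectSegments(ep, rejectionPolicy("amplitude", -150, 150,
                                            roi = c("E2", "E3")))
  expect_false(2 %in% which(!keptTrials(roi$epochs)))
  expect_true(4 %in% which(!keptTrials(roi$epochs)))
  expect_error(rejectSegments(ep, rejectionPolicy("amplitude",
                                                  roi = "nope")),
               "policy error")
})

test_that("rejection is monotone in the amplitude bounds and ROI size", {
  set.seed(15)
  arr <- array(rnorm(40 * 4 * 80, sd = 60), c(40, 4, 80))
  ep <- makeTestEpochs(arr)
  nRej <- vapply(c(100, 150, 200, 250), function(b)
    sum(!keptTrials(rejectSegments(ep,
      rejectionPolicy("amplitude", -b, b))$epochs)), 0L)
  expect_true(all(diff(nRej) <= 0))
  # ROI rejection retains at least as many trials as all-channel rejection
  all4 <- sum(keptTrials(rejectSegments(ep,
    rejectionPolicy("amplitude", -150, 150))$epochs))
  roi2 <- sum(keptTrials(rejectSegments(ep,
    rejectionPolicy("amplitude", -150, 150, roi = c("E1", "E2")))$epochs))
  expect_gte(roi2, all4)
})

test_that("joint-probability rejection flags distributional outliers only", {
  set.seed(16)
  arr <- array(rnorm(30 * 3 * 100), c(30, 3, 100))
  arr[12, 2, ] <- rnorm(100, mean = 0, sd = 8)    # heavy-tailed trial
  ep <- makeTestEpochs(arr)
  res <- rejectSegments(ep, rejectionPolicy("jointprob", jp_sd = 3))
  expect_false(keptTrials(res$epochs)[12])
  # identical trials: none rejected
  same <- array(rep(arr[1, , ], each = 30), c(30, 3, 100))
  res2 <- rejectSegments(makeTestEpochs(same),
                         rejectionPolicy("jointprob", jp_sd = 3))
  expect_true(all(keptTrials(res2$epochs)))
})

test_that("condition splitting partitions trials and keeps the full set", {
  arr <- array(0, c(15, 2, 10))
  ep <- makeTestEpochs(arr)
  ep@conditions <- rep(c("happy_face", "sad_face", "tone"), c(6, 4, 5))
  out <- splitByCondition(ep, list(face = c("happy_face", "sad_face"),
                                   absent = "C"))
  expect_equal(nTrials(out$all), 15)
  expect_equal(nTrials(out$happy_face), 6)
  expect_equal(nTrials(out$face), 10)
  expect_equal(nTrials(out$absent), 0)
  expect_match(paste(out$absent@notes, collapse = " "), "no trials")
  # marker partition conserves trials
  expect_equal(nTrials(out$happy_face) + nTrials(out$sad_face) +
                 nTrials(out$tone), nTrials(out$all))
})
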