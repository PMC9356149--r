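test_that("flatline detection uses a strict > 5 s rule", {
  rate <- 100
  x <- sin(2 * pi * (0:(12 * rate - 1)) / rate)
  expect_false(detectFlatline(x, rate))
  # constant channel
  expect_true(detectFlatline(rep(3, 6 * rate), rate, 5))
  # exactly 5.0 s of flat inside a sinusoid: not flagged (strict >)
  y <- x
  y[1:(5 * rate + 1)] <- y[1]            # 5 s of zero slope
  expect_false(detectFlatline(y, rate, 5))
  y[1:(6 * rate)] <- y[1]
  expect_true(detectFlatline(y, rate, 5))
})

test_that("spectral outliers are flagged asymmetrically (+3.5 / -5 SD)", {
  rate <- 250
  n <- 60 * rate
  data <- t(vapply(1:39, function(i) testPink(n, 100 + i), numeric(n)))
  rec <- newRecording(data, rate)
  expect_length(detectSpectralOutliers(rec), 0)
  # one channel scaled x8 in amplitude: log-power z far above +3.5
  hot <- data; hot[5, ] <- 8 * hot[5, ]
  expect_identical(detectSpectralOutliers(newRecording(hot, rate)), "E5")
  # one channel scaled x0.7 (near-reference attenuation): z > -5, kept
  cool <- data; cool[5, ] <- 0.7 * cool[5, ]
  expect_length(detectSpectralOutliers(newRecording(cool, rate)), 0)
  # all channels identical: zero-variance guard
  same <- data[rep(1, 8), ]
  expect_length(detectSpectralOutliers(newRecording(same, rate)), 0)
})

test_that("line-ratio criterion flags only relatively contaminated channels", {
  rate <- 250
  n <- 60 * rate
  data <- t(vapply(1:20, function(i) testPink(n, 200 + i), numeric(n)))
  rec <- newRecording(data, rate)
  expect_length(detectLineRatioOutliers(rec, line_freq = 60), 0)
  dirty <- data
  dirty[7, ] <- dirty[7, ] + 50 * sin(2 * pi * 60 * (0:(n - 1)) / rate)
  expect_identical(detectLineRatioOutliers(newRecording(dirty, rate),
                                           line_freq = 60), "E7")
  # everyone equally contaminated: relative criterion flags nothing
  allDirty <- data + matrix(50 * sin(2 * pi * 60 * (0:(n - 1)) / rate),
                            20, n, byrow = TRUE)
  expect_length(detectLineRatioOutliers(newRecording(allDirty, rate),
                                        line_freq = 60), 0)
})

test_that("correlation criterion straddles its 0.8 threshold exactly", {
  rate <- 100
  n <- 10 * rate
  t <- (0:(n - 1)) / rate
  s <- sin(2 * pi * 5 * t)                     # integer periods per window
  c5 <- cos(2 * pi * 5 * t)
  mk <- function(a) {
    m <- rbind(s, s, a * s + sqrt(1 - a^2) * c5)
    rownames(m) <- NULL
    m
  }
  # mixture correlation with the sine channels equals the coefficient
  recHi <- newRecording(mk(0.81), rate)
  expect_length(detectLowCorrelation(recHi), 0)
  recLo <- newRecording(mk(0.79), rate)
  expect_identical(detectLowCorrelation(recLo), "E3")
  # independent-noise channel among correlated ones is flagged
  set.seed(5)
  common <- testPink(n, 31)
  data <- rbind(common + 0.3 * rnorm(n), common + 0.3 * rnorm(n),
                common + 0.3 * rnorm(n), rnorm(n))
  expect_identical(detectLowCorrelation(newRecording(data, rate)), "E4")
  # duplicated pair: neither flagged
  dup <- rbind(common, common, common + 0.3 * rnorm(n))
  expect_length(detectLowCorrelation(newRecording(dup, rate)), 0)
})

test_that("composite detector unions criteria with reasons, in order", {
  # 39 channels as in the benchmark design: a single extreme power outlier
  # among n channels can reach at most z = (n-1)/sqrt(n), so the +3.5 SD
  # criterion needs a channel count of this order to bite
  rate <- 250
  clean <- makeBaselineEeg(39, 30, rate, seed = 77)
  rep0 <- detectBadChannels(clean)
  expect_length(rep0$bad, 0)
  expect_equal(rep0$percent_good, 100)

  bad <- unname(eegData(clean))
  bad[2, ] <- 0                                  # flat
  bad[9, ] <- 8 * bad[9, ]                       # spectral outlier
  rep1 <- detectBadChannels(newRecording(bad, rate))
  expect_setequal(rep1$bad, c("E2", "E9"))
  expect_identical(rep1$criteria$E2, "flatline")
  expect_identical(rep1$criteria$E9, "spectrum")
  expect_equal(rep1$percent_good, 100 * 37 / 39)

  # adding a flat channel does not change other flatline verdicts
  more <- unname(rbind(bad, 0))
  rep2 <- detectBadChannels(newRecording(more, rate))
  expect_true(all(c("E2", "E9") %in% rep2$bad))
  expect_identical(rep2$criteria$E40, "flatline")
})

test_that("detection is invariant to channel order and global scaling", {
  rate <- 250
  base0 <- makeBaselineEeg(24, 30, rate, seed = 88)
  data <- unname(eegData(base0))
  data[3, ] <- 8 * data[3, ]
  rec <- newRecording(data, rate)
  base <- detectBadChannels(rec)
  expect_true("E3" %in% base$bad)
  scaled <- newRecording(5 * data, rate)
  expect_setequal(detectBadChannels(scaled)$bad, base$bad)
  set.seed(3)
  perm <- sample(24)
  permuted <- newRecording(data[perm, , drop = FALSE], rate,
                           labels = paste0("E", perm))
  expect_setequal(detectBadChannels(permuted)$bad, base$bad)
})
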