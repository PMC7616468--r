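test_that("Welch spectra are normalized to exactly 100 percent", {
  set.seed(1)
  for (fs in c(1000, 2000)) {
    psd <- welch_psd(rnorm(10 * fs), fs)
    expect_equal(sum(psd$psd_percent), 100, tolerance = 1e-9)
    expect_true(all(psd$freqs >= 2 & psd$freqs <= 60))
  }
  expect_error(welch_psd(rnorm(1000), 1000), "too short")
})

test_that("a 20 Hz tone concentrates power in the beta band", {
  fs <- 1000
  set.seed(2)
  x <- sin(2 * pi * 20 * seq_len(30 * fs) / fs) + 0.05 * rnorm(30 * fs)
  psd <- welch_psd(x, fs)
  beta <- band_power(psd, c(13, 30))
  theta <- band_power(psd, c(4, 8))
  sel <- psd$freqs >= 13 & psd$freqs <= 30
  expect_gt(sum(psd$psd_percent[sel]), 90)
  expect_gt(beta, 10 * theta)
})

test_that("band power behaves as a per-bin mean with sensible edge cases", {
  psd <- list(freqs = seq(2, 60, by = 2), psd_percent = rep(100 / 30, 30))
  expect_equal(band_power(psd, c(4, 8)), band_power(psd, c(30, 60)))
  expect_equal(band_power(psd, c(2, 60)), mean(psd$psd_percent))
  expect_error(band_power(psd, c(8.5, 9.5)), "no bins")
})

test_that("white-noise band percentage is proportional to band width", {
  set.seed(3)
  fs <- 1000
  shares <- replicate(30, {
    psd <- welch_psd(rnorm(20 * fs), fs)
    vapply(list(c(4, 8), c(13, 30), c(30, 60)), function(b) {
      sel <- psd$freqs >= b[1] & psd$freqs <= b[2]
      sum(psd$psd_percent[sel]) / (b[2] - b[1])
    }, numeric(1))
  })
  m <- rowMeans(shares)           # percent of sum power per Hz of band width
  expect_equal(m[2] / m[1], 1, tolerance = 0.1)
  expect_equal(m[3] / m[1], 1, tolerance = 0.1)
})

test_that("channel selection picks the channel with most wake beta power", {
  fs <- 1000
  set.seed(4)
  n <- 60 * fs
  tone <- sin(2 * pi * 20 * seq_len(n) / fs)
  chans <- cbind(rnorm(n), rnorm(n) + tone, rnorm(n))
  expect_equal(select_channel(chans, fs, wake_epochs = 0:1), 2L)
  same <- cbind(chans[, 1], chans[, 1], chans[, 1])
  expect_equal(select_channel(same, fs, wake_epochs = 0:1), 1L)
  expect_error(select_channel(chans, fs, integer(0)), "wake")
})

test_that("magnitude-squared coherence matches identity and SNR oracles", {
  fs <- 1000
  set.seed(5)
  x <- rnorm(120 * fs)
  co <- band_coherence(x, x, fs)
  expect_true(all(co$coherence > 0.999))

  # independent signals: below the Welch bias floor for this segment count
  co0 <- band_coherence(x, rnorm(120 * fs), fs)
  n_seg <- floor((120 * fs - 512) / 512)
  expect_lt(max(co0$bands), 3 / n_seg)

  # y = x + independent noise at SNR 1 -> coherence = SNR/(1+SNR) = 0.5
  y <- x + rnorm(120 * fs)
  co1 <- band_coherence(x, y, fs)
  expect_equal(unname(co1$bands["beta"]), 0.5, tolerance = 0.1)
  expect_error(band_coherence(x, y[-1], fs), "equal length")
})

test_that("burst detection recovers duration ordering and flags degeneracy", {
  mean_dur <- function(dur_ms, seed) {
    cfg <- small_config(seed, coupling = 0, beta_burst_dur_mean = dur_ms)
    r <- generate_recording(cfg)
    rem <- which(r$truth$hypnogram$stages == "R") - 1L
    beta_bursts(r$recording$signals[, 1], 1000, list(REM = rem))$REM$mean_ms
  }
  longs <- vapply(1:4, function(s) mean_dur(300, s), numeric(1))
  shorts <- vapply(1:4, function(s) mean_dur(150, s), numeric(1))
  expect_true(all(longs > shorts))

  fs <- 1000
  x <- sin(2 * pi * 20 * seq_len(90 * fs) / fs)
  expect_warning(bb <- beta_bursts(x, fs, list(all = 0:2)), "degenerate")
  expect_true(bb$all$degenerate)
  expect_error(beta_bursts(x, fs, list(all = 0L)), "60 s")
})

test_that("detected burst intervals overlap the generator's ground truth", {
  r <- generate_recording(small_config(6, coupling = 0))
  rem <- which(r$truth$hypnogram$stages == "R") - 1L
  bb <- beta_bursts(r$recording$signals[, 1], 1000, list(REM = rem))$REM
  # restrict truth bursts to the analysed REM epochs
  span <- cbind(rem * 30, rem * 30 + 30)
  truth <- rembeta:::interval_intersection(r$truth$burst_intervals[["LFP_L1"]], span)
  expect_gt(interval_jaccard(bb$intervals, truth), 0.5)
})
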