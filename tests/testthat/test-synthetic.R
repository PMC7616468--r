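test_that("generation is bit-identical under a fixed seed", {
  a <- generate_recording(small_config(5))
  b <- generate_recording(small_config(5))
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$truth$loss_of_atonia_intervals,
                   b$truth$loss_of_atonia_intervals)

  c1 <- generate_cohort(2, "dystonia", seed = 1,
                        overrides = list(n_hemispheres = 1L,
                                         hypnogram_pattern = data.frame(
                                           stage = c("N2", "R"), n = c(2L, 3L)),
                                         n_isolated = 0L))
  c2 <- generate_cohort(2, "dystonia", seed = 1,
                        overrides = list(n_hemispheres = 1L,
                                         hypnogram_pattern = data.frame(
                                           stage = c("N2", "R"), n = c(2L, 3L)),
                                         n_isolated = 0L))
  expect_identical(c1[[1]]$recording$signals, c2[[1]]$recording$signals)
  expect_identical(c1[[2]]$truth$clinical, c2[[2]]$truth$clinical)
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(fs = 500), "1000 or 2000")
  expect_error(generator_config(coupling_strength = 1.5), "0, 1")
  expect_error(generator_config(coupling_delay_ms = -5), ">= 0")
  expect_error(generator_config(hypnogram_pattern = data.frame(
    stage = "REM", n = 3L)), "invalid")
  expect_error(generate_cohort(3, "parkinson", seed = 1), "unknown profile")
  expect_error(generate_cohort(0, "dystonia", seed = 1), ">= 1")
})

test_that("profile draws respect the group structure", {
  co <- generate_cohort(5, "pd_stn", seed = 7,
                        overrides = list(n_hemispheres = 1L, n_lfp_channels = 1L,
                                         hypnogram_pattern = data.frame(
                                           stage = c("N2", "R"), n = c(2L, 2L)),
                                         n_isolated = 0L))
  expect_true(all(vapply(co, function(s) s$truth$coupling_strength, 1) > 0))
  cd <- generate_cohort(3, "dystonia", seed = 7,
                        overrides = list(n_hemispheres = 1L, n_lfp_channels = 1L,
                                         hypnogram_pattern = data.frame(
                                           stage = c("N2", "R"), n = c(2L, 2L)),
                                         n_isolated = 0L))
  expect_true(all(vapply(cd, function(s) s$truth$coupling_strength, 1) == 0))
})

test_that("beta band power grows with the burst rate", {
  rates <- c(20, 60, 120)
  bp <- sapply(rates, function(rate) {
    vapply(1:4, function(s) {
      r <- generate_recording(small_config(s + rate, coupling = 0,
                                           beta_burst_rate = rate))
      band_power(welch_psd(r$recording$signals[, 1], 1000), c(13, 30))
    }, numeric(1))
  })
  m <- colMeans(bp)
  expect_true(m[1] < m[2] && m[2] < m[3])
  # and the spectrum actually peaks inside the beta band
  r <- generate_recording(small_config(1, coupling = 0, beta_burst_rate = 120))
  psd <- welch_psd(r$recording$signals[, 1], 1000)
  pk <- psd$freqs[which.max(psd$psd_percent * (psd$freqs > 5))]
  expect_true(pk >= 13 && pk <= 30)
})

test_that("EMG envelope rises during loss of atonia", {
  r <- generate_recording(small_config(11, coupling = 0.5))
  tr <- r$truth
  expect_gt(nrow(tr$loss_of_atonia_intervals), 0)
  t200 <- seq_along(tr$emg_env_200) / 200
  rem_mask <- rep(tr$hypnogram$stages == "R", each = 30 * 200)
  loa_mask <- rep(FALSE, length(t200))
  for (j in seq_len(nrow(tr$loss_of_atonia_intervals)))
    loa_mask <- loa_mask | (t200 >= tr$loss_of_atonia_intervals[j, 1] &
                              t200 < tr$loss_of_atonia_intervals[j, 2])
  w <- wilcox.test(tr$emg_env_200[loa_mask],
                   tr$emg_env_200[rem_mask & !loa_mask],
                   alternative = "greater")
  expect_lt(w$p.value, 0.001)
  # episodes fall inside REM epochs
  expect_true(all(loa_mask[rem_mask] | !loa_mask[rem_mask]))
  expect_true(all(!loa_mask[!rem_mask]))
})

test_that("zero coupling leaves the envelopes uncorrelated on average", {
  rhos <- vapply(1:100, function(s) {
    r <- generate_recording(generator_config(
      seed = s, coupling_strength = 0, n_hemispheres = 1L, n_lfp_channels = 1L,
      hypnogram_pattern = data.frame(stage = c("N2", "R"), n = c(2L, 3L)),
      n_isolated = 0L))
    tr <- r$truth
    rem <- which(tr$hypnogram$stages == "R") - 1L
    mean(vapply(rem, function(ep) {
      idx <- (ep * 6000 + 1):((ep + 1) * 6000)
      cor(whiten_ar2(tr$beta_env_200[idx]), whiten_ar2(tr$emg_env_200[idx]),
          method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("the internal envelopes carry the configured transmission delay", {
  for (s in 1:3) {
    r <- generate_recording(generator_config(
      seed = s, coupling_strength = 0.8, n_hemispheres = 1L,
      n_lfp_channels = 1L))
    tr <- r$truth
    rem <- which(tr$hypnogram$stages == "R") - 1L
    lags <- -60:0
    prof <- rowMeans(vapply(rem, function(ep) {
      idx <- (ep * 6000 + 1):((ep + 1) * 6000)
      rembeta:::lag_profile_epoch(tr$beta_env_200[idx], tr$emg_env_200[idx],
                                  lags)
    }, numeric(length(lags))))
    peak_ms <- lags[which.max(abs(prof))] * 5
    expect_lte(abs(peak_ms - (-200)), 5)
  }
})
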