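test_that("wavelet envelopes track analytic amplitude-modulation oracles", {
  fs <- 1000
  t <- seq_len(60 * fs) / fs
  # 20 Hz carrier with 1 Hz AM, depth 0.5: power envelope depth = 2m/(1+m^2)
  x <- (1 + 0.5 * sin(2 * pi * t)) * sin(2 * pi * 20 * t)
  ep <- extract_envelopes(x, numeric(length(x)), fs)
  mid <- ep$beta_env[2000:10000]
  hi <- quantile(mid, 0.975); lo <- quantile(mid, 0.025)
  depth <- (hi - lo) / (hi + lo)
  expect_equal(unname(depth), 0.8, tolerance = 0.08)
  expect_true(all(abs(ep$emg_env) < 1e-12))
  expect_equal(ep$fs, 200)

  # 75 Hz carrier with 2 Hz AM tracked by the EMG-band envelope
  y <- (1 + 0.5 * sin(2 * pi * 2 * t)) * sin(2 * pi * 75 * t)
  ep2 <- extract_envelopes(numeric(length(y)), y, fs)
  mid2 <- ep2$emg_env[2000:10000]
  hi2 <- quantile(mid2, 0.975); lo2 <- quantile(mid2, 0.025)
  expect_equal(unname((hi2 - lo2) / (hi2 + lo2)), 0.8, tolerance = 0.1)

  expect_error(extract_envelopes(x, y, fs = 150), "Nyquist")
})

test_that("AR(2) whitening recovers coefficients and reduces autocorrelation", {
  set.seed(1)
  n <- 5000
  w <- rnorm(n)
  res_w <- whiten_ar2(w)
  expect_lt(max(abs(attr(res_w, "ar"))), 0.05)
  expect_gt(cor(res_w, w[3:n]), 0.99)

  x <- as.numeric(arima.sim(list(ar = c(1.2, -0.4)), n))
  res <- whiten_ar2(x)
  expect_equal(unname(attr(res, "ar")), c(1.2, -0.4), tolerance = 0.05)
  # Yule-Walker oracle agrees
  yw <- ar.yw(x, order.max = 2, aic = FALSE)
  expect_equal(unname(attr(res, "ar")), unname(yw$ar), tolerance = 0.02)
  expect_lt(abs(acf(res, plot = FALSE)$acf[2]), 0.05)

  expect_error(whiten_ar2(rep(3, 100)), "constant")
  expect_error(whiten_ar2(rnorm(10)), "short")
})

test_that("envelope correlation respects Spearman rank invariance", {
  set.seed(2)
  b <- abs(moving_average(rnorm(6000), 50)) + 0.1
  # monotone transform, unwhitened: rho exactly 1
  p_raw <- make_pairs(list(b), list(exp(b)), whiten = FALSE)
  expect_equal(envelope_correlation(p_raw)$rho, 1)
  # after whitening the dependence survives almost fully
  p_wh <- make_pairs(list(b), list(exp(b)), whiten = TRUE)
  expect_gt(envelope_correlation(p_wh)$rho, 0.9)
  # independent series: near zero
  p0 <- make_pairs(list(b), list(abs(moving_average(rnorm(6000), 50)) + 0.1))
  expect_lt(abs(envelope_correlation(p0)$rho), 4 / sqrt(6000))
})

test_that("short epochs are excluded with a warning", {
  set.seed(3)
  pairs <- make_pairs(list(rnorm(6000), rnorm(500)),
                      list(rnorm(6000), rnorm(500)))
  expect_warning(res <- envelope_correlation(pairs), "excluded")
  expect_equal(nrow(res$per_epoch), 1)
})

test_that("block-shuffle surrogate test is deterministic with a p floor", {
  set.seed(4)
  b <- moving_average(rnorm(6000), 30)
  e <- b + 0.05 * moving_average(rnorm(6000), 30)
  pairs <- make_pairs(list(b), list(e))
  st1 <- surrogate_test(pairs, n_surrogates = 200L, seed = 9)
  st2 <- surrogate_test(pairs, n_surrogates = 200L, seed = 9)
  expect_identical(st1$p_surrogate, st2$p_surrogate)
  expect_equal(st1$p_surrogate, 1 / 201)   # strong coupling: floor attained
  expect_error(surrogate_test(pairs, n_surrogates = 50L), "100")
  short <- make_pairs(list(rnorm(300)), list(rnorm(300)))
  expect_error(surrogate_test(short, 200L), "blocks")
})

test_that("constructed envelope shifts are recovered to within one sample", {
  set.seed(5)
  b <- moving_average(rnorm(8000), 25)
  for (shift in c(5, 10, 20, 40, 100)) {
    e <- c(rep(b[1], shift), b[1:(8000 - shift)]) +
      0.02 * moving_average(rnorm(8000), 25)
    pairs <- make_pairs(list(b), list(e))
    lp <- lagged_cross_correlation(pairs, max_lag_ms = 1000, n_surrogates = 0L)
    expect_lte(abs(lp$peak_lag_ms - (-shift * 5)), 5)
  }
  # zero-lag identical envelopes peak at 0
  pairs0 <- make_pairs(list(b), list(b + 0.01 * moving_average(rnorm(8000), 25)))
  lp0 <- lagged_cross_correlation(pairs0, n_surrogates = 0L)
  expect_equal(lp0$peak_lag_ms, 0)
})

test_that("the per-lag surrogate bound brackets the null profile", {
  set.seed(6)
  pairs <- make_pairs(list(moving_average(rnorm(6000), 30)),
                      list(moving_average(rnorm(6000), 30)))
  lp <- lagged_cross_correlation(pairs, max_lag_ms = 500, n_surrogates = 20L,
                                 seed = 2)
  expect_false(any(is.na(lp$profile$surrogate_q975)))
  # under independence only a few lags exceed the 97.5th percentile bound
  expect_lt(mean(lp$profile$rho > lp$profile$surrogate_q975), 0.15)
})

test_that("Granger directionality identifies a constructed driver", {
  set.seed(7)
  n <- 12000
  x <- moving_average(rnorm(n), 40)
  y <- c(rep(0, 40), x[1:(n - 40)]) + 0.2 * moving_average(rnorm(n), 40)
  pairs <- make_pairs(list(x), list(y), whiten = FALSE)
  gc <- granger_direction(pairs)
  expect_gt(gc$gc_beta_to_emg, 3 * gc$gc_emg_to_beta)
  expect_equal(gc$order, 4L)

  p0 <- make_pairs(list(moving_average(rnorm(n), 40)),
                   list(moving_average(rnorm(n), 40)), whiten = FALSE)
  gc0 <- granger_direction(p0)
  expect_lt(gc0$gc_beta_to_emg, 0.05)
  expect_lt(gc0$gc_emg_to_beta, 0.05)
})

test_that("subject rho does not simply mirror beta power", {
  # doubling the burst rate at fixed coupling leaves the envelope
  # correlation in the same range
  rho_at_rate <- function(rate, seeds) vapply(seeds, function(s) {
    r <- generate_recording(small_config(s, coupling = 0.6,
                                         beta_burst_rate = rate))
    envelope_correlation(
      connectivity_pairs(r$recording, r$truth$hypnogram))$rho
  }, numeric(1))
  lo <- rho_at_rate(40, 1:3)
  hi <- rho_at_rate(90, 4:6)
  expect_gt(mean(hi), 0)
  expect_gt(mean(lo), 0)
  expect_lt(abs(mean(hi) - mean(lo)), 3 * sd(c(lo, hi)))
})
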