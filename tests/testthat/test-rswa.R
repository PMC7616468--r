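test_that("integrated EMG is zero for silence and quadratic in gain", {
  fs <- 1000
  seg <- epoch_segments(0:1)
  x <- numeric(60 * fs)
  expect_true(all(integrated_emg(x, fs, seg)$value == 0))
  expect_true(all(emg_variance(x, fs, seg)$value == 0))

  set.seed(1)
  y <- rnorm(60 * fs)
  v1 <- integrated_emg(y, fs, seg)$value
  v3 <- integrated_emg(3 * y, fs, seg)$value
  expect_equal(v3, 9 * v1, tolerance = 1e-10)
})

test_that("a pure 100 Hz sinusoid integrates to ~3 A^2 per 3-s segment", {
  fs <- 1000
  A <- 2.5
  x <- A * sin(2 * pi * 100 * seq_len(90 * fs) / fs)
  seg <- epoch_segments(0:2)
  v <- integrated_emg(x, fs, seg)
  interior <- v$value[v$epoch == 1]        # away from filter edges
  expect_equal(interior, rep(3 * A^2, 10), tolerance = 0.05)
})

test_that("segment variance of bandpassed white noise matches the population value", {
  fs <- 1000
  set.seed(2)
  x <- rnorm(600 * fs)
  pop <- var(rembeta:::emg_band_signal(x, fs))   # long-run population variance
  seg <- epoch_segments(0:9)
  v <- emg_variance(x[1:(300 * fs)], fs, seg)
  expect_equal(mean(v$value), pop, tolerance = 0.1)
})

test_that("integrated EMG and EMG variance rank segments almost identically", {
  r <- generate_recording(mixed_config(3))
  emg <- r$recording$signals[, r$recording$channels$role == "emg"]
  seg <- epoch_segments(which(r$truth$hypnogram$stages != "W") - 1L)
  vi <- integrated_emg(emg, 1000, seg)$value
  vv <- emg_variance(emg, 1000, seg)$value
  expect_gt(cor(vi, vv, method = "spearman"), 0.9)
})

test_that("RSWA threshold is twice the interpolated 5th percentile", {
  expect_equal(rswa_threshold(rep(4.2, 25)), 8.4)
  expect_equal(rswa_threshold(1:100), 11.9)
  expect_equal(rswa_threshold(10 * (1:100)), 119)
  expect_error(rswa_threshold(1:19), ">= 20")
})

test_that("atonia classification thresholds strictly and reports RSWA%", {
  seg <- epoch_segments(0)
  seg$value <- c(1, 3, 5, rep(0.5, 7))
  class(seg) <- c("emg_segments", "data.frame")
  res <- classify_atonia(seg[1:3, ], threshold = 4)
  expect_equal(res$segments$loss_of_atonia, c(FALSE, FALSE, TRUE))
  expect_equal(res$rswa_percent, 100 / 3, tolerance = 1e-10)

  res0 <- classify_atonia(seg, threshold = 10)
  expect_equal(res0$rswa_percent, 0)
  expect_error(classify_atonia(seg, threshold = 0), "> 0")
  # ties count as atonia
  expect_false(classify_atonia(seg[1:1, ], threshold = 1)$segments$loss_of_atonia)
})

test_that("RSWA% is invariant to global EMG gain", {
  r <- generate_recording(mixed_config(4))
  rec2 <- r$recording
  emg_col <- which(rec2$channels$role == "emg")
  rec2$signals[, emg_col] <- 5 * rec2$signals[, emg_col]
  a <- rswa_analysis(r$recording, r$truth$hypnogram)
  b <- rswa_analysis(rec2, r$truth$hypnogram)
  expect_equal(a$rswa_percent, b$rswa_percent)
  expect_equal(b$threshold / a$threshold, 25, tolerance = 1e-6)
})

test_that("NREM dichotomy splits epochs at the median", {
  seg <- epoch_segments(0:3)
  seg$value <- rep(c(1, 2, 3, 4), each = 10)
  class(seg) <- c("emg_segments", "data.frame")
  sp <- split_nrem_by_emg(seg)
  expect_equal(sp$epochs[sp$low], 0:1)
  expect_equal(sp$epochs[sp$high], 2:3)

  seg$value <- rep(2, 40)
  expect_warning(sp2 <- split_nrem_by_emg(seg), "identical")
  expect_true(all(sp2$low))
})

test_that("detected loss-of-atonia intervals recover the ground truth", {
  jac <- vapply(1:3, function(s) {
    r <- generate_recording(generator_config(seed = s, coupling_strength = 0.8,
                                             n_hemispheres = 1L))
    res <- rswa_analysis(r$recording, r$truth$hypnogram)
    interval_jaccard(res$detected_intervals, r$truth$loss_of_atonia_intervals)
  }, numeric(1))
  expect_gt(median(jac), 0.7)
})

test_that("NREM tone at 4x atonia level exceeds every atonic REM epoch", {
  for (s in 1:3) {
    cfg <- mixed_config(s, loss_of_atonia_rate = 0)   # all REM fully atonic
    r <- generate_recording(cfg)
    h <- r$truth$hypnogram
    emg <- r$recording$signals[, r$recording$channels$role == "emg"]
    nrem <- integrated_emg(emg, 1000, epoch_segments(
      which(h$stages %in% c("N1", "N2", "N3")) - 1L))
    rem <- integrated_emg(emg, 1000, epoch_segments(which(h$stages == "R") - 1L))
    nrem_ep <- tapply(nrem$value, nrem$epoch, mean)
    rem_ep <- tapply(rem$value, rem$epoch, mean)
    expect_true(min(nrem_ep) > max(rem_ep))
  }
})
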