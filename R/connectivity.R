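# LFP-beta <-> EMG envelope connectivity: Morlet power envelopes at 200 Hz,
# AR(2) temporal whitening, Spearman envelope correlation with block-shuffle
# surrogate inference, lagged cross-correlation, and time-domain Granger
# directionality.

.morlet_cache <- new.env(parent = emptyenv())

morlet_kernel_fft <- function(nfft, fs, f, n_cycles) {
  key <- paste(nfft, fs, f, n_cycles, sep = "|")
  W <- .morlet_cache[[key]]
  if (is.null(W)) {
    sigma <- n_cycles / (2 * pi * f)
    half <- ceiling(5 * sigma * fs)
    t <- (-half:half) / fs
    w <- exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t)
    w <- w / sqrt(sum(Mod(w)^2))
    W <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
    attr(W, "half") <- half
    .morlet_cache[[key]] <- W
  }
  W
}

#' Band-averaged Morlet wavelet power
#'
#' Instantaneous power from complex Morlet wavelets (fixed number of cycles,
#' L2-normalised), averaged across the 1-Hz-stepped frequencies of a band.
#'
#' @param x signal vector.
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz.
#' @param n_cycles wavelet cycles (default 10).
#' @return power envelope vector, same length as `x`.
#' @export
morlet_band_power <- function(x, fs, freqs, n_cycles = 10) {
  n <- length(x)
  max_sigma <- n_cycles / (2 * pi * min(freqs))
  max_len <- 2L * ceiling(5 * max_sigma * fs) + 1L
  nfft <- next_fast_len(n + max_len)
  X <- stats::fft(c(x, numeric(nfft - n)))
  pow <- numeric(n)
  for (f in freqs) {
    W <- morlet_kernel_fft(nfft, fs, f, n_cycles)
    half <- attr(W, "half")
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    pow <- pow + Mod(conv[(half + 1):(half + n)])^2
  }
  pow / length(freqs)
}

#' Extract LFP-beta and EMG power envelopes at 200 Hz
#'
#' Both signals are decimated to 200 Hz (zero-phase anti-alias lowpass at
#' 95 Hz so the 60-90 Hz EMG band survives), then 10-cycle Morlet power is
#' averaged over 13-30 Hz (LFP) and 60-90 Hz (EMG) in 1-Hz steps.
#'
#' @param lfp,emg equal-length signals at `fs`.
#' @param fs original sampling rate, Hz (integer multiple of 200).
#' @param beta_band,emg_band analysis bands, Hz.
#' @param env_fs envelope rate, Hz (default 200).
#' @return `envelope_pair`: `t` (s), `beta_env`, `emg_env`, `fs`, and a
#'   `whitened` flag (FALSE).
#' @export
extract_envelopes <- function(lfp, emg, fs, beta_band = c(13, 30),
                              emg_band = c(60, 90), env_fs = 200) {
  if (length(lfp) != length(emg)) stop("lfp and emg must have equal length")
  if (emg_band[2] >= fs / 2)
    stop("EMG band upper edge ", emg_band[2],
         " Hz is above the Nyquist rate of the original signal")
  dl <- decimate_to(lfp, fs, env_fs, cutoff_frac = 0.475, method = "fft")
  de <- decimate_to(emg, fs, env_fs, cutoff_frac = 0.475, method = "fft")
  beta_env <- morlet_band_power(dl$x, env_fs, seq(beta_band[1], beta_band[2]))
  emg_env <- morlet_band_power(de$x, env_fs, seq(emg_band[1], emg_band[2]))
  structure(list(t = seq_along(beta_env) / env_fs, beta_env = beta_env,
                 emg_env = emg_env, fs = env_fs, whitened = FALSE),
            class = "envelope_pair")
}

#' Temporally whiten a series with an AR(2) model
#'
#' Fits a second-order autoregression by least squares (with intercept) and
#' returns the residual series, reducing the autocorrelation that would
#' otherwise inflate envelope-correlation estimates.
#'
#' @param x numeric series (length >= 50).
#' @return residuals (length `length(x) - 2`) with the fitted coefficients in
#'   attribute `ar`.
#' @export
whiten_ar2 <- function(x) {
  n <- length(x)
  if (n < 50) stop("series too short to whiten (need >= 50 samples)")
  if (stats::sd(x) < 1e-12 * max(abs(x), 1e-300))
    stop("cannot whiten a (near-)constant series")
  y <- x[3:n]
  X <- cbind(1, x[2:(n - 1)], x[1:(n - 2)])
  fit <- stats::lm.fit(X, y)
  structure(as.numeric(fit$residuals), ar = unname(fit$coefficients[2:3]))
}

# Slice a full-recording envelope pair into whitened per-epoch pieces for the
# given 0-based epochs; returns a list of (epoch, beta, emg).
slice_whiten_epochs <- function(env, epochs, epoch_len_s = 30) {
  spl <- as.integer(epoch_len_s * env$fs)
  lapply(epochs, function(e) {
    idx <- (e * spl + 1):((e + 1) * spl)
    list(epoch = e,
         beta = whiten_ar2(env$beta_env[idx]),
         emg = whiten_ar2(env$emg_env[idx]))
  })
}

#' Build whitened REM-epoch envelope pairs for one recording
#'
#' For every hemisphere: select the bipolar LFP channel with highest wake
#' beta power, extract 200-Hz beta and EMG power envelopes over the whole
#' recording, slice out the requested epochs and whiten each epoch's
#' envelopes with [whiten_ar2()].
#'
#' @param recording `bg_recording`.
#' @param h hypnogram.
#' @param epochs 0-based epochs to analyse (default: all REM epochs).
#' @param eligible logical epoch mask applied when `epochs` is NULL.
#' @return `envelope_pairs`: list of entries `(hemisphere, epoch, beta, emg)`
#'   with attribute `env_fs`.
#' @export
connectivity_pairs <- function(recording, h, epochs = NULL,
                               eligible = rep(TRUE, length(h$stages))) {
  if (is.null(epochs)) epochs <- which(h$stages == "R" & eligible) - 1L
  if (!length(epochs)) stop("no epochs to analyse")
  ch <- recording$channels
  emg_col <- which(ch$role == "emg")[1]
  if (is.na(emg_col)) stop("recording has no EMG channel")
  emg <- recording$signals[, emg_col]
  wake <- which(h$stages == "W") - 1L
  out <- list()
  for (hemi in unique(stats::na.omit(ch$hemisphere[ch$role == "lfp"]))) {
    cols <- which(ch$role == "lfp" & ch$hemisphere %in% hemi)
    sel <- if (length(cols) > 1 && length(wake)) {
      cols[select_channel(recording$signals[, cols, drop = FALSE],
                          recording$fs, wake)]
    } else cols[1]
    env <- extract_envelopes(recording$signals[, sel], emg, recording$fs)
    pieces <- slice_whiten_epochs(env, epochs)
    for (p in pieces) {
      p$hemisphere <- hemi
      out[[length(out) + 1L]] <- p
    }
  }
  structure(out, class = "envelope_pairs", env_fs = 200)
}

spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# Average a per-entry statistic first over epochs within hemisphere, then
# over hemispheres (the subject-level aggregation used throughout).
average_epochs_hemispheres <- function(values, hemispheres) {
  mean(tapply(values, hemispheres, mean))
}

#' Subject-level Spearman envelope correlation
#'
#' Spearman correlation between the whitened beta and EMG envelopes of each
#' epoch, averaged over epochs within hemisphere and then over hemispheres.
#'
#' @param pairs `envelope_pairs` from [connectivity_pairs()].
#' @param min_epoch_s epochs shorter than this many seconds are excluded with
#'   a warning.
#' @return list: `rho` (subject level), `per_epoch` data.frame.
#' @export
envelope_correlation <- function(pairs, min_epoch_s = 10) {
  env_fs <- attr(pairs, "env_fs")
  keep <- vapply(pairs, function(p) length(p$beta) >= min_epoch_s * env_fs,
                 logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " epoch(s) shorter than ", min_epoch_s, " s excluded")
    pairs <- pairs[keep]
  }
  if (!length(pairs)) stop("no epochs long enough for envelope correlation")
  rho_e <- vapply(pairs, function(p) spearman(p$beta, p$emg), numeric(1))
  hemi <- vapply(pairs, `[[`, character(1), "hemisphere")
  ep <- vapply(pairs, `[[`, numeric(1), "epoch")
  list(rho = average_epochs_hemispheres(rho_e, hemi),
       per_epoch = data.frame(hemisphere = hemi, epoch = ep, rho = rho_e))
}

# Contiguous block index list for one epoch: full blocks of `block` samples,
# remainder folded into the last block.
block_indices <- function(n, block) {
  nb <- n %/% block
  if (nb < 2) stop("epoch shorter than 2 shuffle blocks")
  starts <- (0:(nb - 1)) * block + 1
  ends <- c(starts[-1] - 1, n)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

rank_std <- function(x) {
  r <- rank(x)
  (r - mean(r)) / stats::sd(r)
}

#' Block-shuffle surrogate test of the envelope correlation
#'
#' The null distribution is built by permuting the order of contiguous
#' `block_len_s`-second blocks of each epoch's whitened EMG envelope
#' (preserving its autocorrelation, destroying cross-coupling) and
#' recomputing the subject-level correlation.  Two-tailed p with the +1
#' correction: p = (1 + #\{|rho_surr| >= |rho_emp|\}) / (n_surrogates + 1).
#'
#' @param pairs `envelope_pairs`.
#' @param n_surrogates number of shuffles (>= 100; default 200).
#' @param block_len_s shuffle block length in seconds (default 1).
#' @param seed RNG seed for the shuffles.
#' @return list: `rho` (empirical, on the block-tiled samples),
#'   `p_surrogate`, `surrogate_rho` (vector).
#' @details Each epoch is trimmed to a whole number of blocks (the sub-block
#'   remainder, under 1 s per epoch, is discarded) so that permuting block
#'   order leaves block positions aligned; the correlation then reduces to a
#'   permuted trace of the block-level cross-product matrix, which makes
#'   hundreds of surrogates cheap.  The empirical correlation entering the
#'   test is computed on the same trimmed samples for exchangeability.
#' @export
surrogate_test <- function(pairs, n_surrogates = 200L, block_len_s = 1,
                           seed = 1L) {
  if (n_surrogates < 100) stop("need at least 100 surrogates")
  env_fs <- attr(pairs, "env_fs")
  block <- as.integer(block_len_s * env_fs)
  set.seed(seed)
  hemi <- vapply(pairs, `[[`, character(1), "hemisphere")
  emp_e <- numeric(length(pairs))
  surr_e <- matrix(0, length(pairs), n_surrogates)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    nb <- length(p$beta) %/% block
    if (nb < 2) stop("epoch shorter than 2 shuffle blocks")
    nt <- nb * block
    rb <- rank_std(p$beta[1:nt])
    re <- rank_std(p$emg[1:nt])
    emp_e[k] <- sum(rb * re) / (nt - 1)
    # C[k, j] = cross-product of EMG block k against the beta samples at
    # block position j; a block permutation s gives sum_j C[s(j), j]
    C <- crossprod(matrix(re, block, nb), matrix(rb, block, nb))
    ord <- vapply(seq_len(n_surrogates), function(s) sample.int(nb),
                  integer(nb))
    picks <- C[cbind(as.vector(ord), rep(seq_len(nb), n_surrogates))]
    surr_e[k, ] <- colSums(matrix(picks, nb, n_surrogates)) / (nt - 1)
  }
  rho_emp <- average_epochs_hemispheres(emp_e, hemi)
  rho_surr <- vapply(seq_len(n_surrogates), function(s)
    average_epochs_hemispheres(surr_e[, s], hemi), numeric(1))
  p <- (1 + sum(abs(rho_surr) >= abs(rho_emp))) / (n_surrogates + 1)
  list(rho = rho_emp, p_surrogate = p, surrogate_rho = rho_surr)
}

# Rank cross-correlation of one epoch at every lag in `lags` (samples):
# the series are ranked once over the full epoch and Pearson correlation is
# taken over each lag's overlap with exact per-overlap moments (cumulative
# sums).  Negative lag = the first series (beta) leads the second (EMG).
lag_profile_epoch <- function(beta, emg, lags) {
  n <- length(beta)
  rb <- rank(beta); re <- rank(emg)
  cb <- cumsum(rb); cb2 <- cumsum(rb^2)
  ce <- cumsum(re); ce2 <- cumsum(re^2)
  rsum <- function(cs, i1, i2) cs[i2] - if (i1 > 1) cs[i1 - 1] else 0
  vapply(lags, function(L) {
    if (L <= 0) { b1 <- 1; b2 <- n + L; e1 <- 1 - L; e2 <- n }
    else        { b1 <- 1 + L; b2 <- n; e1 <- 1; e2 <- n - L }
    m <- b2 - b1 + 1
    sxy <- sum(rb[b1:b2] * re[e1:e2])
    sx <- rsum(cb, b1, b2); sx2 <- rsum(cb2, b1, b2)
    sy <- rsum(ce, e1, e2); sy2 <- rsum(ce2, e1, e2)
    den <- sqrt((sx2 - sx^2 / m) * (sy2 - sy^2 / m))
    if (den <= 0) return(NA_real_)
    (sxy - sx * sy / m) / den
  }, numeric(1))
}

#' Lagged cross-correlation between whitened envelopes
#'
#' Spearman correlation at every integer envelope-sample lag in
#' [-max_lag_ms, +max_lag_ms], averaged over epochs then hemispheres.
#' Negative lags mean the LFP beta envelope leads the EMG envelope.  A
#' per-lag 97.5th-percentile surrogate bound is estimated from the same
#' block-shuffle engine (rank-based, `n_surrogates` shuffles per epoch;
#' set to 0 to skip).
#'
#' @param pairs `envelope_pairs`.
#' @param max_lag_ms lag range, ms (default 1000).
#' @param n_surrogates surrogate profiles per epoch for the bound
#'   (default 20; pooled over epochs they give a stable per-lag quantile).
#' @param block_len_s surrogate block length, s.
#' @param seed RNG seed for the surrogate shuffles.
#' @return `lag_profile`: data.frame `profile` (`lag_ms`, `rho`,
#'   `surrogate_q975`), `peak_lag_ms` (argmax of |rho|), and `surrogates`
#'   (lags x n_surrogates matrix of subject-averaged surrogate profiles,
#'   NULL when skipped).
#' @export
lagged_cross_correlation <- function(pairs, max_lag_ms = 1000,
                                     n_surrogates = 20L, block_len_s = 1,
                                     seed = 1L) {
  env_fs <- attr(pairs, "env_fs")
  K <- as.integer(round(max_lag_ms / 1000 * env_fs))
  n_min <- min(vapply(pairs, function(p) length(p$beta), integer(1)))
  if (n_min < 2 * K) stop("epochs must span at least twice the maximum lag")
  lags <- -K:K
  hemi <- vapply(pairs, `[[`, character(1), "hemisphere")

  prof_e <- vapply(pairs, function(p)
    lag_profile_epoch(p$beta, p$emg, lags), numeric(length(lags)))
  rho <- apply(prof_e, 1, function(v) average_epochs_hemispheres(v, hemi))

  surr <- NULL; q975 <- rep(NA_real_, length(lags))
  if (n_surrogates > 0) {
    set.seed(seed)
    block <- as.integer(block_len_s * env_fs)
    acc <- array(0, c(length(lags), n_surrogates, length(pairs)))
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      n <- length(p$beta)
      rb <- rank_std(p$beta)
      re <- rank_std(p$emg)
      blocks <- block_indices(n, block)
      idx <- vapply(seq_len(n_surrogates), function(s)
        unlist(blocks[sample.int(length(blocks))], use.names = FALSE),
        integer(n))
      RE <- matrix(re[idx], n, n_surrogates)
      for (li in seq_along(lags)) {
        L <- lags[li]
        ib <- if (L <= 0) 1:(n + L) else (1 + L):n
        ie <- if (L <= 0) (1 - L):n else 1:(n - L)
        acc[li, , k] <- as.numeric(crossprod(RE[ie, , drop = FALSE], rb[ib])) /
          (length(ib) - 1)
      }
    }
    surr <- matrix(0, length(lags), n_surrogates)
    for (s in seq_len(n_surrogates)) {
      surr[, s] <- apply(acc[, s, , drop = FALSE], 1, function(v)
        average_epochs_hemispheres(as.numeric(v), hemi))
    }
    q975 <- apply(surr, 1, stats::quantile, 0.975, type = 7)
  }
  peak <- lags[which.max(abs(rho))] / env_fs * 1000
  structure(list(profile = data.frame(lag_ms = lags / env_fs * 1000, rho = rho,
                                      surrogate_q975 = q975),
                 peak_lag_ms = peak, surrogates = surr),
            class = "lag_profile")
}

#' Average lag profiles across subjects
#'
#' @param profiles list of `lag_profile` objects on identical lag grids.
#' @return `lag_profile` with the across-subject mean correlation (and, when
#'   available, the pooled surrogate 97.5th-percentile bound).
#' @export
average_lag_profiles <- function(profiles) {
  lag_ms <- profiles[[1]]$profile$lag_ms
  R <- vapply(profiles, function(p) p$profile$rho, numeric(length(lag_ms)))
  rho <- rowMeans(R)
  surrs <- lapply(profiles, `[[`, "surrogates")
  if (all(!vapply(surrs, is.null, logical(1)))) {
    S <- Reduce(`+`, surrs) / length(surrs)
    q975 <- apply(S, 1, stats::quantile, 0.975, type = 7)
  } else q975 <- rep(NA_real_, length(lag_ms))
  peak <- lag_ms[which.max(abs(rho))]
  structure(list(profile = data.frame(lag_ms = lag_ms, rho = rho,
                                      surrogate_q975 = q975),
                 peak_lag_ms = peak, surrogates = NULL),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  i <- which.max(abs(x$profile$rho))
  cat(sprintf("<lag_profile> peak |rho| = %.3f at %+.0f ms (%s)\n",
              x$profile$rho[i], x$peak_lag_ms,
              if (x$peak_lag_ms < 0) "beta leads EMG" else
                if (x$peak_lag_ms > 0) "EMG leads beta" else "zero lag"))
  invisible(x)
}

#' @export
plot.lag_profile <- function(x, ...) {
  with(x$profile, {
    plot(lag_ms, rho, type = "l", xlab = "lag (ms; negative = beta leads)",
         ylab = "envelope correlation", ...)
    if (!all(is.na(surrogate_q975)))
      graphics::lines(lag_ms, surrogate_q975, lty = 2, col = "grey40")
    graphics::abline(v = x$peak_lag_ms, lty = 3)
  })
  invisible(x)
}

# One-sided OLS Granger fit: does x help predict y at order p?
# Returns log(RSS_restricted / RSS_full) >= 0 up to numerical noise.
gc_one_direction <- function(y, x, p) {
  n <- length(y)
  if (n <= 3 * p) stop("series too short for Granger order ", p)
  idx <- (p + 1):n
  Yl <- vapply(1:p, function(k) y[idx - k], numeric(length(idx)))
  Xl <- vapply(1:p, function(k) x[idx - k], numeric(length(idx)))
  full <- cbind(1, Yl, Xl)
  restr <- cbind(1, Yl)
  qf <- qr(full)
  if (qf$rank < ncol(full))
    stop("singular regression in Granger fit (rank ", qf$rank, " < ",
         ncol(full), "); envelopes may be degenerate")
  rf <- qr.resid(qf, y[idx])
  rr <- qr.resid(qr(restr), y[idx])
  log(max(sum(rr^2), 1e-300) / max(sum(rf^2), 1e-300))
}

#' Time-domain Granger directionality between beta and EMG envelopes
#'
#' The whitened envelopes are decimated to `analysis_fs` (default 20 Hz, so a
#' 200-ms lag is an integral model order of 4) and bivariate autoregressions
#' fitted per epoch; the Granger value for each direction is the log ratio of
#' restricted to full residual variance, averaged over epochs then
#' hemispheres.
#'
#' @param pairs `envelope_pairs` (whitened).
#' @param lag_ms lag horizon, ms (default 200).
#' @param analysis_fs decimated analysis rate, Hz.
#' @return list: `gc_beta_to_emg`, `gc_emg_to_beta`, `order`, `per_epoch`.
#' @export
granger_direction <- function(pairs, lag_ms = 200, analysis_fs = 20) {
  env_fs <- attr(pairs, "env_fs")
  p <- as.integer(round(lag_ms / 1000 * analysis_fs))
  if (p < 1) stop("lag_ms too small for the analysis rate")
  hemi <- vapply(pairs, `[[`, character(1), "hemisphere")
  g_be <- numeric(length(pairs)); g_eb <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    b <- decimate_to(pairs[[k]]$beta, env_fs, analysis_fs)$x
    e <- decimate_to(pairs[[k]]$emg, env_fs, analysis_fs)$x
    g_be[k] <- gc_one_direction(e, b, p)
    g_eb[k] <- gc_one_direction(b, e, p)
  }
  list(gc_beta_to_emg = average_epochs_hemispheres(g_be, hemi),
       gc_emg_to_beta = average_epochs_hemispheres(g_eb, hemi),
       order = p,
       per_epoch = data.frame(
       hemisphere = hemi,
       epoch = vapply(pairs, `[[`, numeric(1), "epoch"),
       gc_beta_to_emg = g_be, gc_emg_to_beta = g_eb))
}

#' Full beta-EMG coupling analysis for one subject
#'
#' Builds whitened REM-epoch envelope pairs and computes the subject-level
#' envelope correlation, its block-shuffle surrogate p, the lagged
#' cross-correlation profile, and Granger directionality.
#'
#' @param recording `bg_recording`.
#' @param h hypnogram.
#' @param eligible logical epoch mask.
#' @param n_surrogates shuffles for the scalar surrogate test.
#' @param max_lag_ms lag range for the cross-correlation profile; set to 0 to
#'   skip the profile.
#' @param lag_surrogates surrogate profiles per epoch for the per-lag bound.
#' @param seed RNG seed for all shuffles.
#' @return `coupling_result`: `rho`, `p_surrogate`, `lag` (a `lag_profile`
#'   or NULL), `peak_lag_ms`, `gc_beta_to_emg`, `gc_emg_to_beta`.
#' @export
beta_emg_coupling <- function(recording, h,
                              eligible = rep(TRUE, length(h$stages)),
                              n_surrogates = 200L, max_lag_ms = 1000,
                              lag_surrogates = 20L, seed = 1L) {
  pairs <- connectivity_pairs(recording, h, eligible = eligible)
  st <- surrogate_test(pairs, n_surrogates = n_surrogates, seed = seed)
  lag <- NULL; peak <- NA_real_
  if (max_lag_ms > 0) {
    lag <- lagged_cross_correlation(pairs, max_lag_ms = max_lag_ms,
                                    n_surrogates = lag_surrogates, seed = seed)
    peak <- lag$peak_lag_ms
  }
  gc <- granger_direction(pairs)
  structure(list(rho = st$rho, p_surrogate = st$p_surrogate, lag = lag,
                 peak_lag_ms = peak, gc_beta_to_emg = gc$gc_beta_to_emg,
                 gc_emg_to_beta = gc$gc_emg_to_beta, n_epochs = length(pairs)),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> rho = %.4f (surrogate p = %.4f)\n",
              x$rho, x$p_surrogate))
  if (!is.na(x$peak_lag_ms))
    cat(sprintf("  peak cross-correlation lag: %+.0f ms\n", x$peak_lag_ms))
  cat(sprintf("  Granger beta->EMG = %.4f, EMG->beta = %.4f\n",
              x$gc_beta_to_emg, x$gc_emg_to_beta))
  invisible(x)
}

#' @rdname beta_emg_coupling
#' @param x a `coupling_result`.
#' @param path JSON output path.
#' @export
write_coupling_json <- function(x, path) {
  jsonlite::write_json(
    list(rho = x$rho, p_surrogate = x$p_surrogate,
         peak_lag_ms = x$peak_lag_ms, gc_beta_to_emg = x$gc_beta_to_emg,
         gc_emg_to_beta = x$gc_emg_to_beta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
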