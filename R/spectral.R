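# LFP spectral features: normalized Welch spectra, band powers, channel
# selection, LFP-EEG magnitude-squared coherence, beta-burst statistics.

#' Canonical frequency bands (Hz)
#'
#' theta 4-8, beta 13-30 (low 13-20, high 20-30), gamma 30-60.
#' @export
spectral_bands <- function() {
  list(theta = c(4, 8), beta = c(13, 30), low_beta = c(13, 20),
       high_beta = c(20, 30), gamma = c(30, 60))
}

#' Normalized Welch power spectral density
#'
#' Welch periodogram with a 1024-sample Hann window and 50% overlap,
#' restricted to 2-60 Hz and normalized so the retained bins sum to 100
#' (percent of sum power).
#'
#' @param x signal vector (length >= 2048 samples).
#' @param fs sampling rate, Hz (1000 or 2000).
#' @param nfft window length in samples.
#' @param fmin,fmax analysis band bounds, Hz.
#' @return list `freqs` (Hz) and `psd_percent` (sums to 100).
#' @export
welch_psd <- function(x, fs, nfft = 1024L, fmin = 2, fmax = 60) {
  if (length(x) < 2L * nfft)
    stop("input too short for Welch PSD: need >= ", 2L * nfft, " samples")
  F <- welch_segments(x, nfft)
  pxx <- rowMeans(Mod(F)^2)
  f <- welch_freqs(fs, nfft)
  keep <- f >= fmin & f <= fmax
  p <- pxx[keep]
  s <- sum(p)
  if (s <= 0) stop("zero power in the analysis band")
  list(freqs = f[keep], psd_percent = 100 * p / s)
}

#' Band power from a normalized spectrum
#'
#' Mean of the normalized PSD bins whose centre frequency lies in the closed
#' band, making the statistic invariant to frequency resolution.
#'
#' @param psd list from [welch_psd()] (`freqs`, `psd_percent`).
#' @param band numeric length-2 interval in Hz, inside [2, 60].
#' @return band power in percent-of-sum-power units.
#' @export
band_power <- function(psd, band) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2], "] contains no bins")
  mean(psd$psd_percent[sel])
}

#' Select the bipolar LFP channel with highest wake beta power
#'
#' Beta (13-30 Hz) band power is averaged over wake epochs for each channel;
#' the channel with the highest mean wins, ties going to the lowest index.
#'
#' @param signals matrix, one column per bipolar LFP channel.
#' @param fs sampling rate, Hz.
#' @param wake_epochs 0-based indices of wake epochs.
#' @param epoch_len_s epoch length, s.
#' @return selected column index (1-based).
#' @export
select_channel <- function(signals, fs, wake_epochs, epoch_len_s = 30) {
  if (!length(wake_epochs)) stop("no wake epochs for channel selection")
  spl <- epoch_len_s * fs
  beta <- spectral_bands()$beta
  score <- numeric(ncol(signals))
  for (c in seq_len(ncol(signals))) {
    bp <- vapply(wake_epochs, function(e) {
      seg <- signals[(e * spl + 1):((e + 1) * spl), c]
      band_power(welch_psd(seg, fs), beta)
    }, numeric(1))
    score[c] <- mean(bp)
  }
  which.max(score)   # which.max returns the first (lowest) index on ties
}

#' LFP-EEG magnitude-squared coherence per band
#'
#' Coherence on 2-60 Hz using the same Welch parameters as [welch_psd()]
#' (1024-sample Hann window, 50% overlap), then averaged within the theta,
#' beta and gamma bands.  Intended for an LFP against the ipsilateral central
#' EEG channel (C3/C4).
#'
#' @param lfp,eeg equal-length signal vectors at the same rate.
#' @param fs sampling rate, Hz.
#' @param nfft window length.
#' @return list `freqs`, `coherence` (per bin, in [0, 1]) and `bands` (named
#'   theta/beta/gamma averages).
#' @export
band_coherence <- function(lfp, eeg, fs, nfft = 1024L) {
  if (length(lfp) != length(eeg)) stop("lfp and eeg must have equal length")
  if (length(lfp) < 2L * nfft) stop("input too short for coherence")
  Fx <- welch_segments(lfp, nfft)
  Fy <- welch_segments(eeg, nfft)
  pxx <- rowMeans(Mod(Fx)^2)
  pyy <- rowMeans(Mod(Fy)^2)
  pxy <- rowMeans(Fx * Conj(Fy))
  msc <- Mod(pxy)^2 / (pxx * pyy)
  f <- welch_freqs(fs, nfft)
  keep <- f >= 2 & f <= 60
  f <- f[keep]; msc <- pmin(pmax(Re(msc[keep]), 0), 1)
  bands <- spectral_bands()[c("theta", "beta", "gamma")]
  bavg <- vapply(bands, function(b) mean(msc[f >= b[1] & f <= b[2]]), numeric(1))
  list(freqs = f, coherence = msc, bands = bavg)
}

#' Beta-burst durations per sleep state
#'
#' The beta amplitude envelope (13-30 Hz zero-phase bandpass, analytic
#' magnitude, 200-ms moving-average smoothing) is thresholded at the given
#' percentile of the state-pooled envelope; a burst is a supra-threshold run
#' lasting at least `min_dur_ms`.
#'
#' @param lfp signal vector.
#' @param fs sampling rate, Hz.
#' @param epochs_by_state named list of 0-based epoch-index vectors (e.g.
#'   `list(REM = ..., NREM = ...)`); each state needs >= 60 s of data.
#' @param threshold_pct envelope percentile defining a burst (default 75).
#' @param min_dur_ms minimum burst duration, ms (default 100).
#' @param smooth_ms envelope smoothing window, ms (default 200).
#' @param epoch_len_s epoch length, s.
#' @return list per state: `durations_ms`, `mean_ms` (NA when no bursts),
#'   `intervals` (global seconds), `threshold`, plus a `degenerate` flag set
#'   when the envelope is (near-)constant so the percentile threshold is
#'   meaningless.
#' @export
beta_bursts <- function(lfp, fs, epochs_by_state, threshold_pct = 75,
                        min_dur_ms = 100, smooth_ms = 200, epoch_len_s = 30) {
  beta <- spectral_bands()$beta
  env_full <- moving_average(
    Mod(analytic_signal(bandpass_filter(lfp, fs, beta[1], beta[2]))),
    as.integer(smooth_ms / 1000 * fs))
  spl <- as.integer(epoch_len_s * fs)
  out <- list()
  for (state in names(epochs_by_state)) {
    eps <- epochs_by_state[[state]]
    if (length(eps) * epoch_len_s < 60)
      stop("state '", state, "' has less than 60 s of data")
    env_list <- lapply(eps, function(e) env_full[(e * spl + 1):((e + 1) * spl)])
    pooled <- unlist(env_list, use.names = FALSE)
    thr <- unname(stats::quantile(pooled, threshold_pct / 100, type = 7))
    # near-constant envelope (robust to filter edge transients): the bulk of
    # the distribution is flat, so a percentile threshold is meaningless
    qs <- stats::quantile(pooled, c(0.01, 0.5, 0.99), type = 7)
    degenerate <- (qs[3] - qs[1]) < 0.01 * max(qs[2], 1e-300)
    if (degenerate)
      warning("near-constant envelope in state '", state,
              "': percentile threshold is degenerate")
    durs <- numeric(0); ivs <- list()
    min_len <- min_dur_ms / 1000 * fs
    for (k in seq_along(eps)) {
      above <- env_list[[k]] >= thr
      r <- rle(above)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      sel <- which(r$values & r$lengths >= min_len)
      if (length(sel)) {
        t0 <- eps[k] * epoch_len_s
        durs <- c(durs, r$lengths[sel] / fs * 1000)
        ivs[[length(ivs) + 1L]] <-
          cbind(t0 + (starts[sel] - 1L) / fs, t0 + ends[sel] / fs)
      }
    }
    ivm <- if (length(ivs)) do.call(rbind, ivs) else matrix(numeric(0), ncol = 2)
    dimnames(ivm) <- list(NULL, c("start", "end"))
    out[[state]] <- list(durations_ms = durs,
                         mean_ms = if (length(durs)) mean(durs) else NA_real_,
                         intervals = ivm, threshold = thr,
                         degenerate = degenerate)
  }
  out
}

#' Per-epoch spectral feature table for one channel
#'
#' Normalized band powers per epoch, the basis of loss-of-atonia vs atonia
#' beta comparisons.
#'
#' @param x signal vector.
#' @param fs sampling rate, Hz.
#' @param epochs 0-based epoch indices.
#' @param epoch_len_s epoch length, s.
#' @return data.frame: epoch plus one column per band of [spectral_bands()].
#' @export
epoch_band_powers <- function(x, fs, epochs, epoch_len_s = 30) {
  spl <- as.integer(epoch_len_s * fs)
  bands <- spectral_bands()
  rows <- lapply(epochs, function(e) {
    psd <- welch_psd(x[(e * spl + 1):((e + 1) * spl)], fs)
    c(epoch = e, vapply(bands, function(b) band_power(psd, b), numeric(1)))
  })
  as.data.frame(do.call(rbind, rows))
}
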