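# Synthetic polysomnography generator: PSG-like multichannel recordings with
# known hypnogram, atonia structure and LFP->EMG envelope coupling.

#' Default hypnogram stage pattern
#'
#' A run-length encoded stage sequence resembling a short recording block with
#' NREM/REM alternation: wake lead-in, a descending NREM period, and three REM
#' periods separated by NREM. 56 epochs (28 min) in total, of which 20 are REM.
#'
#' @return data.frame with columns `stage` and `n` (epochs per run).
#' @export
default_hypnogram_pattern <- function() {
  data.frame(
    stage = c("W", "N1", "N2", "N3", "N2", "R", "N2", "R", "N2", "R"),
    n     = c(4L,  2L,   10L,  6L,   4L,   8L,  6L,   6L,  4L,   6L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic recording generator
#'
#' Signal model: each bipolar LFP channel is 1/f background noise plus
#' transient beta bursts (Hann-windowed sinusoids at `beta_center_freq` with
#' gamma-distributed inter-burst intervals and durations).  Chin EMG is white
#' noise bandpassed 60-160 Hz, amplitude-modulated by a stage-dependent
#' envelope: `emg_nrem_tonus` with slow lognormal variability during
#' wake/NREM, `emg_atonia_level` during REM atonia, and during
#' loss-of-atonia episodes an added excess that mixes the (delayed) LFP beta
#' envelope with independent slow noise in proportion `coupling_strength`.
#' EEG channels are plain 1/f noise.
#'
#' @param fs sampling rate in Hz (1000 or 2000).
#' @param n_hemispheres 1 or 2 recorded hemispheres.
#' @param n_lfp_channels bipolar LFP channels per hemisphere (default 3).
#' @param beta_center_freq centre frequency of beta bursts, Hz.
#' @param beta_burst_rate burst rate on the strongest channel, bursts/min.
#' @param beta_burst_dur_mean mean burst duration, ms.
#' @param beta_burst_amp peak burst amplitude relative to the unit-variance
#'   1/f background.
#' @param channel_burst_scale per-channel multipliers of the burst rate,
#'   length `n_lfp_channels`; graded so channel selection is identifiable.
#' @param one_over_f_exponent spectral exponent of the background.
#' @param emg_nrem_tonus,emg_atonia_level,emg_loa_excess EMG envelope levels
#'   (arbitrary amplitude units) for NREM/wake tone, REM atonia, and the
#'   added tone during loss-of-atonia episodes.
#' @param emg_loa_tonic_frac fraction of the loss-of-atonia excess that is
#'   sustained (tonic); the remainder is phasic, following the coupling
#'   drive.
#' @param beta_loa_boost extra beta-burst rate during (delay-shifted)
#'   loss-of-atonia episodes, as a multiple of the baseline rate per unit
#'   coupling strength (beta elevation accompanies atonia loss in the
#'   coupled, parkinsonian regime; zero coupling leaves bursting
#'   homogeneous).
#' @param emg_tonus_log_sd log-sd of the slow lognormal NREM tone variability.
#' @param loss_of_atonia_rate episodes per minute of REM sleep.
#' @param loss_of_atonia_dur_mean mean episode duration, s (exponential).
#' @param coupling_strength mixing weight in [0,1] of the delayed LFP beta
#'   envelope in the loss-of-atonia EMG excess; 0 makes EMG independent of
#'   the LFP.
#' @param coupling_delay_ms delay of the beta envelope before it drives the
#'   EMG envelope, ms (beta leads EMG).
#' @param coupling_smooth_ms smoothing window applied to the beta envelope
#'   before it enters the EMG drive, ms (muscular activations blur the
#'   burst waveform slightly; kept short so burst-scale structure carries
#'   the transmission delay).
#' @param scorer2_error_rate fraction of epochs the simulated second scorer
#'   mislabels.
#' @param hypnogram_pattern run-length stage pattern (see
#'   [default_hypnogram_pattern()]).
#' @param n_isolated number of deliberately isolated epochs injected into the
#'   hypnogram (single epochs differing from both neighbours).
#' @param seed integer RNG seed; the generator is fully deterministic given it.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(fs = 1000,
                             n_hemispheres = 2L,
                             n_lfp_channels = 3L,
                             beta_center_freq = 20,
                             beta_burst_rate = 60,
                             beta_burst_dur_mean = 200,
                             beta_burst_amp = 3,
                             channel_burst_scale = NULL,
                             one_over_f_exponent = 1.2,
                             emg_nrem_tonus = 4,
                             emg_atonia_level = 1,
                             emg_loa_excess = 4,
                             emg_loa_tonic_frac = 0.3,
                             beta_loa_boost = 0.8,
                             emg_tonus_log_sd = 0.6,
                             loss_of_atonia_rate = 1.6,
                             loss_of_atonia_dur_mean = 10,
                             coupling_strength = 0.5,
                             coupling_delay_ms = 200,
                             coupling_smooth_ms = 50,
                             scorer2_error_rate = 0.128,
                             hypnogram_pattern = default_hypnogram_pattern(),
                             n_isolated = 2L,
                             seed = 1L) {
  if (!fs %in% c(1000, 2000)) stop("fs must be 1000 or 2000 Hz")
  if (!n_hemispheres %in% 1:2) stop("n_hemispheres must be 1 or 2")
  if (n_lfp_channels < 1) stop("need at least one LFP channel per hemisphere")
  if (is.null(channel_burst_scale))
    channel_burst_scale <- c(1, 0.6, 0.3, 0.15, 0.1)[seq_len(n_lfp_channels)]
  if (length(channel_burst_scale) != n_lfp_channels)
    stop("channel_burst_scale must have one entry per LFP channel")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  if (coupling_delay_ms < 0) stop("coupling_delay_ms must be >= 0")
  rates <- c(beta_burst_rate, loss_of_atonia_rate, emg_nrem_tonus,
             emg_atonia_level, emg_loa_excess, scorer2_error_rate)
  if (any(rates < 0)) stop("rates and levels must be >= 0")
  stages <- c("W", "N1", "N2", "N3", "R")
  if (!is.data.frame(hypnogram_pattern) ||
      !all(c("stage", "n") %in% names(hypnogram_pattern)) ||
      !all(hypnogram_pattern$stage %in% stages) ||
      any(hypnogram_pattern$n < 1))
    stop("invalid hypnogram_pattern: need data.frame(stage in {W,N1,N2,N3,R}, n >= 1)")
  cfg <- as.list(environment())
  cfg$stages <- NULL
  cfg$rates <- NULL
  structure(cfg, class = "generator_config")
}

stage_alternative <- function(s) if (s == "N2") "R" else "N2"

build_hypnogram_stages <- function(pattern, n_isolated) {
  stages <- rep(pattern$stage, pattern$n)
  n <- length(stages)
  if (n_isolated > 0) {
    # interior positions inside homogeneous runs of length >= 3
    ok <- which(vapply(2:(n - 1), function(i)
      stages[i - 1] == stages[i] && stages[i] == stages[i + 1], logical(1))) + 1L
    picked <- integer(0)
    for (i in sample(ok)) {
      if (length(picked) >= n_isolated) break
      if (all(abs(i - picked) > 2L)) picked <- c(picked, i)
    }
    for (i in picked) stages[i] <- stage_alternative(stages[i])
  }
  stages
}

corrupt_hypnogram <- function(stages, rate) {
  n <- length(stages)
  k <- round(rate * n)
  if (k == 0) return(stages)
  idx <- sample(n, k)
  all_stages <- c("W", "N1", "N2", "N3", "R")
  for (i in idx) stages[i] <- sample(setdiff(all_stages, stages[i]), 1)
  stages
}

# Poisson loss-of-atonia episodes within contiguous REM runs.
# Returns half-open [start, end) intervals in seconds, global recording time.
draw_loa_intervals <- function(stages, rate_per_min, dur_mean_s, epoch_len = 30) {
  r <- rle(stages)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values == "R")) {
    t0 <- (starts[k] - 1L) * epoch_len
    t1 <- ends[k] * epoch_len
    dur_min <- (t1 - t0) / 60
    n_ep <- stats::rpois(1, rate_per_min * dur_min)
    if (n_ep == 0) next
    s <- sort(stats::runif(n_ep, t0, t1))
    d <- pmax(stats::rexp(n_ep, 1 / dur_mean_s), 2)
    e <- pmin(s + d, t1)
    # merge overlaps within the run
    iv <- cbind(s, e)
    merged <- iv[1, , drop = FALSE]
    if (n_ep > 1) for (j in 2:n_ep) {
      if (iv[j, 1] <= merged[nrow(merged), 2]) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[j, 2])
      } else merged <- rbind(merged, iv[j, ])
    }
    out[[length(out) + 1L]] <- merged
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

# Burst train on one channel: a stationary train (gamma inter-burst gaps,
# gamma durations, Hann envelopes) plus extra bursts at `boost_rate_per_min`
# inside `boost_intervals` (beta elevation during loss-of-atonia episodes).
# Returns the amplitude envelope (length n) and merged burst intervals (s).
draw_burst_train <- function(n, fs, rate_per_min, dur_mean_ms, amp,
                             boost_intervals = NULL, boost_rate_per_min = 0) {
  env <- numeric(n)
  iv <- list()
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (rate_per_min <= 0 || amp <= 0) return(list(env = env, intervals = empty))
  mean_gap <- pmax(60 / rate_per_min - dur_mean_ms / 1000, 0.05)
  t <- stats::rgamma(1, shape = 2, scale = mean_gap / 2)
  dur_s <- n / fs
  draw_dur <- function() max(stats::rgamma(1, shape = 3,
                                           scale = dur_mean_ms / 3000), 0.05)
  add_burst <- function(t, d) {
    i0 <- floor(t * fs) + 1L
    i1 <- min(floor((t + d) * fs), n)
    len <- i1 - i0 + 1L
    if (len <= 3) return(NULL)
    hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
    env[i0:i1] <<- pmax(env[i0:i1], amp * hann)
    c(t, t + d)
  }
  while (t < dur_s) {
    d <- min(draw_dur(), dur_s - t)
    r <- add_burst(t, d)
    if (!is.null(r)) iv[[length(iv) + 1L]] <- r
    t <- t + d + stats::rgamma(1, shape = 2, scale = mean_gap / 2)
  }
  if (!is.null(boost_intervals) && nrow(boost_intervals) &&
      boost_rate_per_min > 0) {
    for (j in seq_len(nrow(boost_intervals))) {
      t0 <- max(boost_intervals[j, 1], 0); t1 <- min(boost_intervals[j, 2], dur_s)
      if (t1 <= t0) next
      n_extra <- stats::rpois(1, boost_rate_per_min * (t1 - t0) / 60)
      if (!n_extra) next
      for (tb in stats::runif(n_extra, t0, t1)) {
        d <- min(draw_dur(), dur_s - tb)
        r <- add_burst(tb, d)
        if (!is.null(r)) iv[[length(iv) + 1L]] <- r
      }
    }
  }
  ivm <- if (length(iv)) merge_intervals(do.call(rbind, iv)) else empty
  dimnames(ivm) <- list(NULL, c("start", "end"))
  list(env = env, intervals = ivm)
}

# Slow positive modulation, lognormal with mean 1: exp(sd*z - sd^2/2) where z
# is white noise smoothed over `smooth_s` seconds and rescaled to unit sd.
# Generated at 200 Hz and step-upsampled: the modulation is far slower than
# the 5-ms step, so the staircase is immaterial.
slow_lognormal <- function(n, fs, log_sd, smooth_s = 5) {
  q <- max(1L, as.integer(fs / 200))
  nl <- ceiling(n / q)
  z <- moving_average(stats::rnorm(nl), as.integer(smooth_s * fs / q))
  s <- stats::sd(z)
  if (s < 1e-12) return(rep(1, n))
  rep(exp(log_sd * z / s - log_sd^2 / 2), each = q)[1:n]
}

# Unit-sd slow noise (same construction, additive form).
slow_noise <- function(n, fs, smooth_s = 2) {
  q <- max(1L, as.integer(fs / 200))
  nl <- ceiling(n / q)
  z <- moving_average(stats::rnorm(nl), as.integer(smooth_s * fs / q))
  s <- stats::sd(z)
  if (s < 1e-12) return(numeric(n))
  rep(z / s, each = q)[1:n]
}

#' Generate one synthetic PSG recording with ground truth
#'
#' @param config a [generator_config()].
#' @return list with elements `recording` (class `bg_recording`: `signals`
#'   matrix, `fs`, `channels` table with name/role/hemisphere) and `truth`
#'   (class `bg_truth`: hypnogram of both scorers, loss-of-atonia intervals,
#'   per-channel beta-burst intervals, the coupling parameters, and the
#'   generator's internal beta and EMG envelopes subsampled to 200 Hz, which
#'   serve as analysis oracles).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  fs <- config$fs
  stages <- build_hypnogram_stages(config$hypnogram_pattern, config$n_isolated)
  stages2 <- corrupt_hypnogram(stages, config$scorer2_error_rate)
  n_epochs <- length(stages)
  n <- n_epochs * 30L * fs

  loa <- draw_loa_intervals(stages, config$loss_of_atonia_rate,
                            config$loss_of_atonia_dur_mean)

  hemis <- c("L", "R")[seq_len(config$n_hemispheres)]
  n_lfp <- config$n_lfp_channels
  sig <- list(); ch_name <- character(0); ch_role <- character(0)
  ch_hemi <- character(0)
  burst_iv <- list()
  tt <- seq_len(n) / fs

  # beta bursting is elevated inside loss-of-atonia episodes, shifted earlier
  # by the transmission delay (beta leads the EMG consequence)
  delay_s <- config$coupling_delay_ms / 1000
  boost_iv <- if (nrow(loa)) cbind(pmax(loa[, 1] - delay_s, 0),
                                   pmax(loa[, 2] - delay_s, 0)) else loa
  boost_rate <- config$beta_burst_rate * config$beta_loa_boost *
    config$coupling_strength

  # the strongest (first) bipolar channel's burst train is shared across
  # hemispheres (bilaterally synchronous beta bursting, the parkinsonian
  # regime); weaker channels burst independently
  bt_shared <- draw_burst_train(n, fs, config$beta_burst_rate,
                                config$beta_burst_dur_mean,
                                config$beta_burst_amp,
                                boost_intervals = boost_iv,
                                boost_rate_per_min = boost_rate)
  for (h in hemis) {
    for (c in seq_len(n_lfp)) {
      bt <- if (c == 1L) bt_shared else
        draw_burst_train(n, fs,
                         config$beta_burst_rate * config$channel_burst_scale[c],
                         config$beta_burst_dur_mean, config$beta_burst_amp,
                         boost_intervals = boost_iv,
                         boost_rate_per_min = boost_rate *
                           config$channel_burst_scale[c])
      phase <- stats::runif(1, 0, 2 * pi)
      x <- one_over_f_noise(n, fs, config$one_over_f_exponent)
      on <- which(bt$env > 0)              # bursts are sparse; add only there
      if (length(on))
        x[on] <- x[on] + bt$env[on] *
          sin(2 * pi * config$beta_center_freq * tt[on] + phase)
      nm <- sprintf("LFP_%s%d", h, c)
      sig[[nm]] <- x
      ch_name <- c(ch_name, nm); ch_role <- c(ch_role, "lfp")
      ch_hemi <- c(ch_hemi, h)
      burst_iv[[nm]] <- bt$intervals
    }
  }
  drive_env <- bt_shared$env

  # Coupling drive: lightly smoothed (preserving burst-scale structure),
  # mean-normalised, delayed beta envelope.
  d <- moving_average(drive_env, as.integer(config$coupling_smooth_ms / 1000 * fs))
  md <- mean(d)
  d_norm <- if (md > 1e-12) d / md else d
  nd <- as.integer(round(config$coupling_delay_ms / 1000 * fs))
  d_del <- if (nd > 0) c(rep(d_norm[1], nd), d_norm[seq_len(n - nd)]) else d_norm

  # EMG envelope
  stage_per_sample <- rep(stages, each = 30L * fs)
  E <- numeric(n)
  nrem_mask <- stage_per_sample %in% c("W", "N1", "N2", "N3")
  tone <- config$emg_nrem_tonus *
    slow_lognormal(n, fs, config$emg_tonus_log_sd, smooth_s = 5)
  E[nrem_mask] <- tone[nrem_mask]
  rem_mask <- stage_per_sample == "R"
  rem_fluct <- 1 + 0.2 * slow_noise(n, fs, smooth_s = 2)
  E[rem_mask] <- config$emg_atonia_level * pmax(rem_fluct[rem_mask], 0.2)

  # loss-of-atonia excess: tonic floor + phasic part mixing the delayed beta
  # drive with independent slow noise in proportion to coupling strength
  eta <- slow_lognormal(n, fs, 0.5, smooth_s = 2)
  cs <- config$coupling_strength
  tf <- config$emg_loa_tonic_frac
  m_t <- tf + (1 - tf) * (cs * d_del + (1 - cs) * eta)
  if (nrow(loa)) for (j in seq_len(nrow(loa))) {
    i0 <- floor(loa[j, 1] * fs) + 1L
    i1 <- min(ceiling(loa[j, 2] * fs), n)
    E[i0:i1] <- E[i0:i1] + config$emg_loa_excess * m_t[i0:i1]
  }
  E <- pmax(E, 0.05)

  emg_carrier <- bandlimited_noise(n, fs, 60, 160)
  sig[["EMG_chin"]] <- E * emg_carrier + 0.02 * stats::rnorm(n)
  ch_name <- c(ch_name, "EMG_chin"); ch_role <- c(ch_role, "emg")
  ch_hemi <- c(ch_hemi, NA_character_)

  for (h in hemis) {
    nm <- if (h == "L") "EEG_C3" else "EEG_C4"
    sig[[nm]] <- one_over_f_noise(n, fs, config$one_over_f_exponent)
    ch_name <- c(ch_name, nm); ch_role <- c(ch_role, "eeg")
    ch_hemi <- c(ch_hemi, h)
  }

  signals <- do.call(cbind, sig)
  recording <- structure(list(
    signals = signals,
    fs = fs,
    channels = data.frame(name = ch_name, role = ch_role,
                          hemisphere = ch_hemi, stringsAsFactors = FALSE)
  ), class = "bg_recording")

  sub <- seq(1L, n, by = fs %/% 200L)
  truth <- structure(list(
    hypnogram = hypnogram(stages),
    hypnogram_scorer2 = hypnogram(stages2),
    loss_of_atonia_intervals = loa,
    burst_intervals = burst_iv,
    coupling_delay_ms = config$coupling_delay_ms,
    coupling_strength = config$coupling_strength,
    beta_env_200 = d_norm[sub],       # undelayed drive envelope at 200 Hz
    emg_env_200 = E[sub],
    config = config
  ), class = "bg_truth")

  list(recording = recording, truth = truth)
}

#' @export
print.bg_recording <- function(x, ...) {
  cat(sprintf("<bg_recording> %d channels x %.0f s at %d Hz\n",
              ncol(x$signals), nrow(x$signals) / x$fs, x$fs))
  cat("  channels:", paste(x$channels$name, collapse = ", "), "\n")
  invisible(x)
}

cohort_profiles <- c("pd_gpi", "pd_stn", "dystonia")

# Per-profile parameter draws; PD profiles couple the EMG to the LFP beta
# envelope with substantial loss of atonia, dystonia has zero coupling and
# little atonia loss.
draw_profile_params <- function(profile) {
  switch(profile,
    pd_gpi = list(coupling_strength = stats::runif(1, 0.45, 0.9),
                  loss_of_atonia_rate = stats::runif(1, 1.2, 2.2),
                  beta_burst_rate = stats::runif(1, 70, 110),
                  beta_burst_dur_mean = stats::runif(1, 150, 250)),
    pd_stn = list(coupling_strength = stats::runif(1, 0.45, 0.9),
                  loss_of_atonia_rate = stats::runif(1, 1.2, 2.2),
                  beta_burst_rate = stats::runif(1, 60, 100),
                  beta_burst_dur_mean = stats::runif(1, 150, 250)),
    dystonia = list(coupling_strength = 0,
                    loss_of_atonia_rate = stats::runif(1, 0.25, 0.65),
                    beta_burst_rate = stats::runif(1, 15, 35),
                    beta_burst_dur_mean = stats::runif(1, 100, 200)),
    stop("unknown profile '", profile, "' (use ",
         paste(cohort_profiles, collapse = "/"), ")")
  )
}

#' Generate a cohort of synthetic subjects
#'
#' Subject-level generator parameters are drawn per clinical profile
#' (`pd_gpi` and `pd_stn`: positive LFP-EMG coupling, frequent loss of
#' atonia, strong beta bursting; `dystonia`: zero coupling, sparse loss of
#' atonia, weak beta).  Clinical scores are attached to each subject's truth:
#' `rbdsq` (0-13) drawn as a noisy increasing function of coupling strength
#' and `video_rbd` (0-4, movement 0-3 plus vocalisation 0-1).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param profile one of `"pd_gpi"`, `"pd_stn"`, `"dystonia"`.
#' @param seed cohort seed; per-subject seeds are derived from it, so the
#'   cohort is fully reproducible.
#' @param overrides named list of [generator_config()] arguments forced on
#'   every subject (applied after the profile draw).
#' @return list of per-subject lists `(recording, truth)`; each truth carries
#'   `clinical` (rbdsq, video_rbd) and `profile`.
#' @export
generate_cohort <- function(n_subjects, profile, seed, overrides = list()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(profile) != 1 || !profile %in% cohort_profiles)
    stop("unknown profile '", profile, "' (use ",
         paste(cohort_profiles, collapse = "/"), ")")
  set.seed(seed)
  params <- vector("list", n_subjects)
  clin <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- draw_profile_params(profile)
    rbdsq <- round(2 + 10 * p$coupling_strength + stats::rnorm(1, 0, 1.5))
    rbdsq <- min(13L, max(0L, as.integer(rbdsq)))
    movement <- min(3L, max(0L, as.integer(round(3 * p$coupling_strength +
                                                   stats::rnorm(1, 0, 0.5)))))
    vocal <- as.integer(stats::runif(1) < 0.3 * p$coupling_strength)
    params[[i]] <- p
    clin[[i]] <- list(rbdsq = rbdsq, video_rbd = movement + vocal,
                      movement = movement, vocalisation = vocal)
  }
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    subject_seed <- (as.numeric(seed) * 1000 + i * 7) %% 2147483647
    args <- c(params[[i]], list(seed = as.integer(subject_seed)))
    args[names(overrides)] <- overrides
    cfg <- do.call(generator_config, args)
    r <- generate_recording(cfg)
    r$truth$clinical <- clin[[i]]
    r$truth$profile <- profile
    r$subject <- sprintf("%s_%02d", profile, i)
    out[[i]] <- r
  }
  out
}
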