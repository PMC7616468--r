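# End-to-end pipeline: hypnogram preparation -> RSWA -> spectral features ->
# connectivity -> group statistics, with per-stage bookkeeping.

# Beta band power of 3-s REM segments split by atonia label, averaged across
# the hemispheres' selected LFP channels.
beta_power_by_atonia <- function(recording, rswa_res, sel_cols) {
  seg <- rswa_res$segments
  fs <- recording$fs
  bp <- vapply(seq_len(nrow(seg)), function(j) {
    i0 <- floor(seg$t_start_s[j] * fs) + 1
    i1 <- floor(seg$t_end_s[j] * fs)
    mean(vapply(sel_cols, function(c)
      band_power(welch_psd(recording$signals[i0:i1, c], fs),
                 spectral_bands()$beta), numeric(1)))
  }, numeric(1))
  list(loss = if (any(seg$loss_of_atonia)) mean(bp[seg$loss_of_atonia]) else NA_real_,
       atonia = if (any(!seg$loss_of_atonia)) mean(bp[!seg$loss_of_atonia]) else NA_real_,
       per_segment = bp)
}

# NREM epoch beta power split by the median-EMG dichotomy.
beta_power_by_nrem_emg <- function(recording, rswa_res, sel_cols) {
  split <- split_nrem_by_emg(rswa_res$nrem_segments)
  fs <- recording$fs
  bp <- vapply(split$epochs, function(e) {
    idx <- (e * 30 * fs + 1):((e + 1) * 30 * fs)
    mean(vapply(sel_cols, function(c)
      band_power(welch_psd(recording$signals[idx, c], fs),
                 spectral_bands()$beta), numeric(1)))
  }, numeric(1))
  list(low = mean(bp[split$low]), high = if (any(split$high))
    mean(bp[split$high]) else NA_real_)
}

# Mean beta-burst duration inside vs outside detected loss-of-atonia
# intervals (bursts assigned by midpoint).
burst_durations_by_atonia <- function(recording, h, eligible, rswa_res, sel_col) {
  rem <- which(h$stages == "R" & eligible) - 1L
  bb <- beta_bursts(recording$signals[, sel_col], recording$fs,
                    list(REM = rem))$REM
  if (!nrow(bb$intervals))
    return(list(loss = NA_real_, atonia = NA_real_))
  mid <- rowMeans(bb$intervals)
  loa <- rswa_res$detected_intervals
  in_loa <- vapply(mid, function(m)
    nrow(loa) > 0 && any(m >= loa[, 1] & m < loa[, 2]), logical(1))
  list(loss = if (any(in_loa)) mean(bb$durations_ms[in_loa]) else NA_real_,
       atonia = if (any(!in_loa)) mean(bb$durations_ms[!in_loa]) else NA_real_)
}

selected_lfp_columns <- function(recording, h) {
  ch <- recording$channels
  wake <- which(h$stages == "W") - 1L
  vapply(unique(stats::na.omit(ch$hemisphere[ch$role == "lfp"])), function(hemi) {
    cols <- which(ch$role == "lfp" & ch$hemisphere %in% hemi)
    if (length(cols) > 1 && length(wake))
      cols[select_channel(recording$signals[, cols, drop = FALSE],
                          recording$fs, wake)]
    else cols[1]
  }, integer(1))
}

#' Analyse one subject end to end
#'
#' Runs hypnogram preparation (two-scorer consensus when a second hypnogram
#' is available, isolated-epoch dropping, REM-NREM matching), RSWA detection,
#' spectral features (beta power by atonia state, NREM EMG dichotomy,
#' beta-burst durations), and beta-EMG envelope connectivity.
#'
#' @param recording `bg_recording`.
#' @param h primary hypnogram.
#' @param h2 optional second scorer's hypnogram.
#' @param clinical optional list with `rbdsq` and `video_rbd`.
#' @param group group label for the feature row.
#' @param seed seed for surrogate shuffles.
#' @param n_surrogates surrogate count for the envelope-correlation test.
#' @param max_lag_ms cross-correlation lag range (0 skips the profile).
#' @param lag_surrogates per-epoch surrogate profiles for the per-lag bound.
#' @return list: `features` (one-row data.frame), `rswa`, `coupling`,
#'   `pairing`, `bookkeeping`.
#' @export
analyze_subject <- function(recording, h, h2 = NULL, clinical = NULL,
                            group = NA_character_, seed = 1L,
                            n_surrogates = 200L, max_lag_ms = 1000,
                            lag_surrogates = 10L) {
  prep <- prepare_hypnogram(h, h2)
  elig <- prep$eligible
  rswa_res <- rswa_analysis(recording, h, elig)
  sel <- selected_lfp_columns(recording, h)
  bpa <- beta_power_by_atonia(recording, rswa_res, sel)
  bpn <- beta_power_by_nrem_emg(recording, rswa_res, sel)
  bd <- burst_durations_by_atonia(recording, h, elig, rswa_res, sel[1])
  coupling <- beta_emg_coupling(recording, h, elig, n_surrogates = n_surrogates,
                                max_lag_ms = max_lag_ms,
                                lag_surrogates = lag_surrogates, seed = seed)
  features <- data.frame(
    group = group,
    rswa_percent = rswa_res$rswa_percent,
    beta_power_atonia = bpa$atonia, beta_power_loss = bpa$loss,
    beta_power_nrem_low = bpn$low, beta_power_nrem_high = bpn$high,
    burst_dur_atonia = bd$atonia, burst_dur_loss = bd$loss,
    rho = coupling$rho, p_surrogate = coupling$p_surrogate,
    peak_lag_ms = coupling$peak_lag_ms,
    gc_beta_to_emg = coupling$gc_beta_to_emg,
    gc_emg_to_beta = coupling$gc_emg_to_beta,
    rbdsq = if (!is.null(clinical)) clinical$rbdsq else NA_integer_,
    video_rbd = if (!is.null(clinical)) clinical$video_rbd else NA_integer_,
    stringsAsFactors = FALSE)
  list(features = features, rswa = rswa_res, coupling = coupling,
       pairing = prep$pairing, bookkeeping = prep$bookkeeping)
}

#' Subject feature table for a synthetic cohort
#'
#' @param cohort list from [generate_cohort()].
#' @param seed base seed for surrogate shuffles (subject index is added).
#' @param ... passed to [analyze_subject()].
#' @return data.frame, one row per subject.
#' @export
cohort_features <- function(cohort, seed = 1L, ...) {
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    a <- analyze_subject(s$recording, s$truth$hypnogram,
                         h2 = s$truth$hypnogram_scorer2,
                         clinical = s$truth$clinical,
                         group = s$truth$profile, seed = seed + i, ...)
    cbind(subject = s$subject, a$features)
  })
  do.call(rbind, rows)
}

#' Group-level statistics on a cohort feature table
#'
#' Within-group paired comparisons (beta power and burst duration in loss of
#' atonia vs atonia, Granger beta-to-EMG vs EMG-to-beta), between-group
#' Mann-Whitney comparisons of RSWA% and envelope correlation (PD pooled vs
#' dystonia), and Spearman correlations of connectivity with clinical scores
#' per group.
#'
#' @param features data.frame from [cohort_features()] (possibly several
#'   groups bound together).
#' @return tidy data.frame: comparison, group, statistic, p, n.
#' @export
group_statistics <- function(features) {
  out <- list()
  add <- function(comparison, group, statistic, p, n)
    out[[length(out) + 1L]] <<- data.frame(comparison = comparison,
                                           group = group,
                                           statistic = statistic, p = p, n = n)
  for (g in unique(features$group)) {
    d <- features[features$group == g, ]
    if (nrow(d) < 5) {
      warning("group '", g, "' has fewer than 5 subjects; paired tests skipped")
      next
    }
    ok <- stats::complete.cases(d[, c("beta_power_loss", "beta_power_atonia")])
    if (sum(ok) >= 5) {
      t1 <- paired_test(d$beta_power_loss[ok], d$beta_power_atonia[ok])
      add("beta_power_loss_vs_atonia", g, t1$statistic, t1$p, sum(ok))
    }
    ok <- stats::complete.cases(d[, c("burst_dur_loss", "burst_dur_atonia")])
    if (sum(ok) >= 5) {
      t2 <- paired_test(d$burst_dur_loss[ok], d$burst_dur_atonia[ok])
      add("burst_dur_loss_vs_atonia", g, t2$statistic, t2$p, sum(ok))
    }
    t3 <- paired_test(d$gc_beta_to_emg, d$gc_emg_to_beta)
    add("gc_beta_vs_emg", g, t3$statistic, t3$p, nrow(d))
    if (!all(is.na(d$rbdsq)) && nrow(d) >= 5) {
      cc <- tryCatch(clinical_correlation(d, "rho", "rbdsq"),
                     error = function(e) NULL)
      if (!is.null(cc) && !is.na(cc$rho))
        add("rho_vs_rbdsq", g, cc$rho, cc$p, cc$n)
    }
  }
  pd <- features[features$group %in% c("pd_gpi", "pd_stn"), ]
  dys <- features[features$group == "dystonia", ]
  if (nrow(pd) >= 3 && nrow(dys) >= 3) {
    u1 <- unpaired_test(pd$rswa_percent, dys$rswa_percent)
    add("rswa_pd_vs_dystonia", "all", u1$statistic, u1$p, nrow(pd) + nrow(dys))
    u2 <- unpaired_test(pd$rho, dys$rho)
    add("rho_pd_vs_dystonia", "all", u2$statistic, u2$p, nrow(pd) + nrow(dys))
  }
  if (!length(out)) return(data.frame(comparison = character(0),
                                      group = character(0),
                                      statistic = numeric(0), p = numeric(0),
                                      n = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline on one or more synthetic cohorts
#'
#' Executes, per subject, hypnogram preparation, RSWA detection, spectral
#' features and connectivity, then the group statistics, writing all result
#' tables under `out_dir`: `features.csv`, `group_stats.csv`, per-subject
#' coupling JSON, and a `log.csv` with per-stage epoch bookkeeping.  Every
#' output is reproducible from the seeds recorded in `run_info.json`.
#'
#' @param cohorts named list of cohorts (each from [generate_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param seed seed for all surrogate randomness.
#' @param ... passed to [analyze_subject()].
#' @return invisibly, a list with `features`, `stats`, `log`.
#' @export
run_pipeline <- function(cohorts, out_dir, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- list(); logs <- list()
  for (cname in names(cohorts)) {
    cohort <- cohorts[[cname]]
    for (i in seq_along(cohort)) {
      s <- cohort[[i]]
      a <- analyze_subject(s$recording, s$truth$hypnogram,
                           h2 = s$truth$hypnogram_scorer2,
                           clinical = s$truth$clinical,
                           group = s$truth$profile, seed = seed + i, ...)
      feats[[length(feats) + 1L]] <- cbind(subject = s$subject, a$features)
      bk <- a$bookkeeping
      logs[[length(logs) + 1L]] <- data.frame(
        subject = s$subject, total_epochs = bk$total,
        consistent = bk$consistent,
        consistent_fraction = bk$consistent_fraction,
        dropped_isolated = bk$dropped_isolated, n_pairs = bk$n_pairs)
      write_coupling_json(a$coupling,
                          file.path(out_dir, paste0(s$subject, "_coupling.json")))
    }
  }
  features <- do.call(rbind, feats)
  log <- do.call(rbind, logs)
  n_groups <- length(unique(features$group))
  stats_tab <- if (nrow(features) < 2) {
    warning("single-subject run: group statistics skipped")
    NULL
  } else group_statistics(features)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(log, file.path(out_dir, "log.csv"), row.names = FALSE)
  if (!is.null(stats_tab))
    utils::write.csv(stats_tab, file.path(out_dir, "group_stats.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_subjects = nrow(features),
                            groups = unique(features$group)),
                       file.path(out_dir, "run_info.json"), auto_unbox = TRUE)
  invisible(list(features = features, stats = stats_tab, log = log))
}
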