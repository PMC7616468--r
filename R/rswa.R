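# REM sleep without atonia (RSWA) detection from chin EMG: integrated EMG per
# 3-s segment, individualized 2 x P5 NREM threshold, atonia classification.

#' Tile epochs into 3-s analysis segments
#'
#' Each 30-s epoch is split into ten non-overlapping 3-s segments aligned to
#' the epoch start.
#'
#' @param epochs 0-based epoch indices.
#' @param epoch_len_s,seg_len_s epoch and segment lengths in seconds.
#' @return data.frame: `epoch`, `segment` (0-9 within epoch), `t_start_s`,
#'   `t_end_s` (half-open).
#' @export
epoch_segments <- function(epochs, epoch_len_s = 30, seg_len_s = 3) {
  k <- as.integer(epoch_len_s / seg_len_s)
  d <- expand.grid(segment = 0:(k - 1), epoch = as.integer(epochs))
  d$t_start_s <- d$epoch * epoch_len_s + d$segment * seg_len_s
  d$t_end_s <- d$t_start_s + seg_len_s
  d[, c("epoch", "segment", "t_start_s", "t_end_s")]
}

emg_band_signal <- function(emg, fs) {
  if (fs < 400) stop("fs must be >= 400 Hz for the 80-160 Hz EMG band")
  bandpass_filter(emg, fs, 80, 160, order = 4L)
}

segment_slice_index <- function(seg_row, fs, n) {
  i0 <- floor(seg_row[["t_start_s"]] * fs) + 1
  i1 <- min(floor(seg_row[["t_end_s"]] * fs), n)
  if (i1 < i0) stop("segment outside recording")
  i0:i1
}

#' Integrated EMG per 3-s segment
#'
#' The EMG is bandpassed 80-160 Hz (zero-phase), its power envelope taken as
#' the squared magnitude of the analytic signal (or, with
#' `method = "rectified"`, rectification followed by 100-ms smoothing, for
#' sensitivity analysis), and the area under the envelope integrated over
#' each segment by the trapezoidal rule (units: amplitude^2 x s).
#'
#' @param emg chin EMG signal vector.
#' @param fs sampling rate, Hz (>= 400).
#' @param segments data.frame from [epoch_segments()].
#' @param method `"analytic"` (default) or `"rectified"`.
#' @return `emg_segments`: the segments table with a `value` column and a
#'   `flagged` column marking segments shorter than the 1-s filter-settling
#'   margin.
#' @export
integrated_emg <- function(emg, fs, segments, method = c("analytic", "rectified")) {
  method <- match.arg(method)
  xb <- emg_band_signal(emg, fs)
  env <- if (method == "analytic") {
    Mod(analytic_signal(xb))^2
  } else {
    moving_average(abs(xb), as.integer(0.1 * fs))^2
  }
  n <- length(env)
  vals <- numeric(nrow(segments))
  flagged <- logical(nrow(segments))
  for (j in seq_len(nrow(segments))) {
    idx <- segment_slice_index(segments[j, ], fs, n)
    flagged[j] <- length(idx) < fs          # < 1 s: filter settling margin
    vals[j] <- trapz_uniform(env[idx], 1 / fs)
  }
  out <- segments
  out$value <- vals
  out$flagged <- flagged
  class(out) <- c("emg_segments", "data.frame")
  attr(out, "statistic") <- paste0("integrated_emg_", method)
  out
}

#' EMG variance per segment
#'
#' Alternative muscular-activity statistic: per-segment variance of the
#' 80-160 Hz bandpassed EMG.
#'
#' @inheritParams integrated_emg
#' @return `emg_segments` as in [integrated_emg()].
#' @export
emg_variance <- function(emg, fs, segments) {
  xb <- emg_band_signal(emg, fs)
  n <- length(xb)
  vals <- numeric(nrow(segments))
  flagged <- logical(nrow(segments))
  for (j in seq_len(nrow(segments))) {
    idx <- segment_slice_index(segments[j, ], fs, n)
    flagged[j] <- length(idx) < fs
    vals[j] <- stats::var(xb[idx])
  }
  out <- segments
  out$value <- vals
  out$flagged <- flagged
  class(out) <- c("emg_segments", "data.frame")
  attr(out, "statistic") <- "emg_variance"
  out
}

#' Individualized RSWA threshold
#'
#' Twice the 5th percentile of the subject's own NREM integrated-EMG values
#' (linear-interpolation percentile convention).
#'
#' @param nrem_values `emg_segments` (or numeric vector) of NREM segment
#'   values; at least 20 segments are required for a stable percentile.
#' @return threshold in the same units as the values.
#' @export
rswa_threshold <- function(nrem_values) {
  v <- if (is.data.frame(nrem_values)) nrem_values$value else nrem_values
  if (length(v) < 20) stop("need >= 20 NREM segments for a stable 5th percentile")
  2 * unname(stats::quantile(v, 0.05, type = 7))
}

#' Classify REM segments as atonia vs loss of atonia
#'
#' A REM segment shows loss of atonia when its value exceeds the threshold
#' strictly (ties count as atonia).  RSWA% is the percentage of REM time
#' without atonia among all REM time.
#'
#' @param rem_values `emg_segments` of REM segments.
#' @param threshold from [rswa_threshold()]; must be > 0.
#' @return `rswa_result`: `threshold`, `segments` (with logical
#'   `loss_of_atonia`), `rswa_percent`, and `detected_intervals` (merged
#'   half-open intervals of supra-threshold segments, seconds).
#' @export
classify_atonia <- function(rem_values, threshold) {
  if (!nrow(rem_values)) stop("no REM segments to classify")
  if (threshold <= 0) stop("threshold must be > 0")
  seg <- as.data.frame(rem_values)
  seg$loss_of_atonia <- seg$value > threshold
  hit <- seg[seg$loss_of_atonia, c("t_start_s", "t_end_s"), drop = FALSE]
  iv <- if (nrow(hit)) merge_intervals(as.matrix(hit)) else
    matrix(numeric(0), ncol = 2)
  dimnames(iv) <- list(NULL, c("start", "end"))
  structure(list(threshold = threshold, segments = seg,
                 rswa_percent = 100 * mean(seg$loss_of_atonia),
                 detected_intervals = iv),
            class = "rswa_result")
}

#' @export
print.rswa_result <- function(x, ...) {
  cat(sprintf(
    "<rswa_result> RSWA %.1f%% of REM time (%d/%d segments above threshold %.3g)\n",
    x$rswa_percent, sum(x$segments$loss_of_atonia), nrow(x$segments),
    x$threshold))
  invisible(x)
}

#' Dichotomize NREM epochs by EMG activity
#'
#' Epoch-level integrated EMG (mean over the epoch's segments) is compared to
#' the median across epochs: below or equal goes to the low-EMG half, above
#' to the high-EMG half.
#'
#' @param nrem_values `emg_segments` of NREM segments.
#' @return list with `epochs`, `epoch_emg`, `low` and `high` logical masks
#'   per epoch.
#' @export
split_nrem_by_emg <- function(nrem_values) {
  ep_val <- tapply(nrem_values$value, nrem_values$epoch, mean)
  if (length(ep_val) < 2) stop("need >= 2 NREM epochs to dichotomize")
  med <- stats::median(ep_val)
  low <- ep_val <= med
  if (all(low)) warning("all NREM epochs have identical EMG; high-EMG half is empty")
  list(epochs = as.integer(names(ep_val)), epoch_emg = as.numeric(ep_val),
       low = unname(low), high = unname(!low))
}

#' Full RSWA analysis of one recording
#'
#' Computes integrated EMG on 3-s segments of all eligible REM and NREM
#' epochs, derives the individualized threshold from the NREM segments
#' (optionally only the matched NREM epochs), and classifies REM atonia.
#'
#' @param recording a `bg_recording` (needs an `emg`-role channel).
#' @param h hypnogram.
#' @param eligible logical epoch mask (default: all epochs).
#' @param nrem_reference `"all"` eligible NREM epochs (default) or
#'   `"matched"` (only epochs in `pairing`).
#' @param pairing `epoch_pairing`, required for `nrem_reference="matched"`.
#' @param statistic `"integrated"` or `"variance"`.
#' @return `rswa_result` with extra elements `nrem_segments` and
#'   `rem_segments`.
#' @export
rswa_analysis <- function(recording, h, eligible = rep(TRUE, length(h$stages)),
                          nrem_reference = c("all", "matched"), pairing = NULL,
                          statistic = c("integrated", "variance")) {
  nrem_reference <- match.arg(nrem_reference)
  statistic <- match.arg(statistic)
  emg_ch <- which(recording$channels$role == "emg")[1]
  if (is.na(emg_ch)) stop("recording has no EMG channel")
  emg <- recording$signals[, emg_ch]
  fs <- recording$fs

  rem_epochs <- which(h$stages == "R" & eligible) - 1L
  nrem_epochs <- if (nrem_reference == "matched") {
    if (is.null(pairing)) stop("nrem_reference='matched' needs a pairing")
    sort(pairing$pairs$nrem_epoch)
  } else which(h$stages %in% NREM_STAGES & eligible) - 1L
  if (!length(rem_epochs)) stop("no eligible REM epochs")
  if (!length(nrem_epochs)) stop("no eligible NREM epochs")

  fun <- if (statistic == "integrated") integrated_emg else emg_variance
  nrem_seg <- fun(emg, fs, epoch_segments(nrem_epochs))
  rem_seg <- fun(emg, fs, epoch_segments(rem_epochs))
  thr <- rswa_threshold(nrem_seg)
  res <- classify_atonia(rem_seg, thr)
  res$nrem_segments <- nrem_seg
  res$rem_segments <- rem_seg
  res
}

#' @rdname rswa_analysis
#' @param x an `rswa_result`.
#' @param path CSV path (`epoch,segment,t_start_s,t_end_s,integrated_emg,label`).
#' @export
write_rswa_csv <- function(x, path) {
  d <- x$segments
  utils::write.csv(
    data.frame(epoch = d$epoch, segment = d$segment, t_start_s = d$t_start_s,
               t_end_s = d$t_end_s, integrated_emg = d$value,
               label = ifelse(d$loss_of_atonia, "loss_of_atonia", "atonia")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
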