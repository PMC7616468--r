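# Minimal EDF/EDF+ writer and reader for multichannel PSG recordings.
# EDF: 256-byte fixed-layout ASCII header, 256 bytes of per-signal header
# fields, then data records of int16 little-endian samples.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)            # left-justified, space padded
}

num_field <- function(x, width)
  pad_field(trimws(formatC(x, format = "fg", digits = 7)), width)

#' Write a recording to an EDF file
#'
#' One-second data records; each channel is scaled to its own symmetric
#' physical range and quantized to 16 bits.  Channel roles are encoded in the
#' labels (`LFP_L1`, `EMG_chin`, `EEG_C3`, ...), which [read_edf()] maps back
#' to roles.
#'
#' @param recording `bg_recording` whose duration is a whole number of
#'   seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signals
  fs <- recording$fs
  n <- nrow(sig)
  if (n %% fs != 0) stop("recording length must be a whole number of seconds")
  n_rec <- n %/% fs
  ns <- ncol(sig)
  pmax_ <- pmax(apply(abs(sig), 2, max), 1e-6)

  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    num_field(256 * (ns + 1), 8),
    pad_field("EDF", 44),
    num_field(n_rec, 8),
    num_field(1, 8),
    num_field(ns, 4)
  )
  per_sig <- paste0(
    paste(vapply(recording$channels$name, pad_field, "", width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(-pmax_, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_, num_field, "", width = 8), collapse = ""),
    paste(rep(num_field(-32767, 8), ns), collapse = ""),
    paste(rep(num_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(num_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, per_sig)), con)

  # digital samples, record-major then channel-major within record
  dig <- matrix(0L, n, ns)
  for (c in seq_len(ns))
    dig[, c] <- as.integer(round(sig[, c] / pmax_[c] * 32767))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Channel roles are inferred from label prefixes (`LFP`, `EMG`, `EEG`);
#' hemispheres from `L`/`R` in LFP labels and `C3`/`C4` for EEG.  All
#' channels must share one sampling rate.
#'
#' @param path EDF file.
#' @return `bg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  as.numeric(rd(8))                     # header bytes (unused)
  rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(as.numeric(rd(4)))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # physical dim
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # prefiltering
  spr <- as.integer(as.numeric(vapply(seq_len(ns), function(i) rd(8), "")))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates per channel are not supported")
  fs <- spr[1] / rec_dur
  n <- n_rec * spr[1]
  sig <- matrix(0, n, ns, dimnames = list(NULL, labels))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = spr[1] * ns, size = 2L,
                     endian = "little")
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    sig[rows, ] <- matrix(block, spr[1], ns)
  }
  for (c in seq_len(ns))
    sig[, c] <- pmin_[c] + (sig[, c] - dmin[c]) * scale[c]

  role <- rep("other", ns)
  role[startsWith(labels, "LFP")] <- "lfp"
  role[startsWith(labels, "EMG")] <- "emg"
  role[startsWith(labels, "EEG")] <- "eeg"
  hemi <- rep(NA_character_, ns)
  hemi[grepl("^LFP_L", labels)] <- "L"
  hemi[grepl("^LFP_R", labels)] <- "R"
  hemi[grepl("C3", labels)] <- "L"
  hemi[grepl("C4", labels)] <- "R"
  structure(list(signals = sig, fs = fs,
                 channels = data.frame(name = labels, role = role,
                                       hemisphere = hemi,
                                       stringsAsFactors = FALSE)),
            class = "bg_recording")
}

#' Read and validate a recording for the pipeline
#'
#' Wraps [read_edf()] with the pipeline's channel-role and sampling-rate
#' checks: an LFP and an EMG channel must be present, and the rate must be
#' 1000 or 2000 Hz unless overridden.
#'
#' @param path EDF file.
#' @param allow_any_fs proceed with a warning on other sampling rates.
#' @return `bg_recording`.
#' @export
read_recording <- function(path, allow_any_fs = FALSE) {
  rec <- read_edf(path)
  for (need in c("lfp", "emg")) {
    if (!any(rec$channels$role == need))
      stop("recording is missing a channel with role '", need, "'")
  }
  if (!rec$fs %in% c(1000, 2000)) {
    if (allow_any_fs) warning("unusual sampling rate ", rec$fs, " Hz; proceeding")
    else stop("unsupported sampling rate ", rec$fs,
              " Hz (expected 1000 or 2000; set allow_any_fs to override)")
  }
  rec
}

#' Write generator ground truth as JSON
#'
#' @param truth `bg_truth` from [generate_recording()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    hypnogram = truth$hypnogram$stages,
    hypnogram_scorer2 = truth$hypnogram_scorer2$stages,
    loss_of_atonia_intervals = unname(apply(truth$loss_of_atonia_intervals, 1,
                                            function(r) list(start = r[[1]], end = r[[2]]))),
    coupling_delay_ms = truth$coupling_delay_ms,
    coupling_strength = truth$coupling_strength,
    clinical = truth$clinical
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
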