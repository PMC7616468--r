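# Hypnogram preparation: scorer consensus, isolated-epoch dropping, and
# REM-NREM epoch matching without replacement.

SLEEP_STAGES <- c("W", "N1", "N2", "N3", "R")
NREM_STAGES <- c("N1", "N2", "N3")

#' Construct a hypnogram
#'
#' A hypnogram is one stage label per 30-s epoch, 0-based epoch indexing.
#'
#' @param stages character vector of labels in {W, N1, N2, N3, R}.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) < 1) stop("hypnogram needs at least one epoch")
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_len_s = 30), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = SLEEP_STAGES))
  cat(sprintf("<hypnogram> %d epochs (%.1f min): %s\n", length(x$stages),
              length(x$stages) / 2,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Read / write hypnogram CSV
#'
#' CSV format: columns `epoch_index` (0-based) and `stage`.
#'
#' @param path file path.
#' @param h hypnogram to write.
#' @return `read_hypnogram_csv` returns a `hypnogram`.
#' @export
read_hypnogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(d)))
    stop("hypnogram CSV needs columns epoch_index,stage")
  hypnogram(d$stage[order(d$epoch_index)])
}

#' @rdname read_hypnogram_csv
#' @export
write_hypnogram_csv <- function(h, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_along(h$stages) - 1L, stage = h$stages),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-scorer consensus mask
#'
#' Epochs are eligible for analysis only when both scorers assigned the same
#' stage.
#'
#' @param h1,h2 hypnograms of equal length.
#' @return list with `mask` (logical per epoch, TRUE = consistent) and
#'   `consistent_fraction`.
#' @export
consensus_mask <- function(h1, h2) {
  stopifnot(inherits(h1, "hypnogram"), inherits(h2, "hypnogram"))
  if (length(h1$stages) != length(h2$stages))
    stop("hypnogram lengths differ (", length(h1$stages), " vs ",
         length(h2$stages), ")")
  mask <- h1$stages == h2$stages
  list(mask = mask, consistent_fraction = mean(mask))
}

#' Drop isolated epochs
#'
#' An isolated epoch carries a stage label different from both of its
#' neighbours (e.g. a single N2 epoch between two REM epochs) and is unlikely
#' to represent a stable sleep state.  Boundary epochs have a single
#' neighbour and are dropped only if they differ from it.
#'
#' @param h hypnogram.
#' @param eligible logical mask (e.g. from [consensus_mask()]); isolated
#'   epochs are marked ineligible, all other eligibility is preserved.
#' @return updated logical mask.
#' @export
drop_isolated <- function(h, eligible = rep(TRUE, length(h$stages))) {
  s <- h$stages
  n <- length(s)
  if (length(eligible) != n) stop("mask length must equal hypnogram length")
  iso <- logical(n)
  if (n >= 2) {
    iso[1] <- s[1] != s[2]
    iso[n] <- s[n] != s[n - 1]
  }
  if (n >= 3) {
    i <- 2:(n - 1)
    iso[i] <- s[i] != s[i - 1] & s[i] != s[i + 1]
  }
  eligible & !iso
}

# Minimum-total-distance assignment of every element of `a` to a distinct
# element of `b` (|a| <= |b|, both sorted ascending, costs |a_i - b_j|).
# For absolute-difference costs on a line an optimal non-crossing (monotone)
# assignment exists, so a simple dynamic programme suffices; ties are broken
# toward matching (earlier b elements).
assign_min_distance <- function(a, b) {
  k <- length(a); m <- length(b)
  dp <- matrix(Inf, k + 1, m + 1)
  dp[1, ] <- 0
  for (i in seq_len(k)) for (j in i:m) {
    take <- dp[i, j] + abs(a[i] - b[j])
    skip <- dp[i + 1, j]
    dp[i + 1, j + 1] <- min(take, skip)
  }
  # backtrack, preferring the match when costs tie
  pairs <- matrix(0L, k, 2)
  i <- k; j <- m
  while (i >= 1) {
    if (j > i && dp[i + 1, j] <= dp[i, j] + abs(a[i] - b[j])) {
      j <- j - 1
    } else {
      pairs[i, ] <- c(a[i], b[j])
      i <- i - 1; j <- j - 1
    }
  }
  pairs
}

#' Match REM epochs to nearest NREM epochs without replacement
#'
#' Builds temporally comparable REM-NREM epoch pairs: each eligible REM epoch
#' is assigned a distinct eligible NREM epoch so that the total epoch-index
#' distance is minimal (computed exactly by a non-crossing dynamic
#' programme); among equal-cost assignments the non-crossing one matching
#' earlier NREM epochs is returned.  NREM substages are treated as one
#' homogeneous stage unless `substage` names a specific one.
#'
#' @param h hypnogram.
#' @param eligible logical epoch mask.
#' @param substage optional single NREM substage ("N1"/"N2"/"N3") to restrict
#'   the NREM pool (substage-resolved sensitivity analysis).
#' @return object of class `epoch_pairing`: data.frame `pairs`
#'   (`rem_epoch`, `nrem_epoch`, 0-based, plus `distance_min`),
#'   `mean_distance_min`, and `unmatched_rem` (indices of REM epochs left
#'   unmatched when NREM epochs run out).
#' @export
match_rem_nrem <- function(h, eligible = rep(TRUE, length(h$stages)),
                           substage = NULL) {
  s <- h$stages
  if (length(eligible) != length(s)) stop("mask length must equal hypnogram length")
  nrem_pool <- if (is.null(substage)) NREM_STAGES else
    match.arg(substage, NREM_STAGES)
  rem_idx <- which(s == "R" & eligible) - 1L          # 0-based
  nrem_idx <- which(s %in% nrem_pool & eligible) - 1L
  if (!length(rem_idx)) stop("no eligible REM epochs to match")
  if (!length(nrem_idx)) stop("no eligible NREM epochs to match against")

  rem_idx <- sort(rem_idx); nrem_idx <- sort(nrem_idx)
  unmatched <- integer(0)
  if (length(rem_idx) <= length(nrem_idx)) {
    pm <- assign_min_distance(rem_idx, nrem_idx)
  } else {
    # NREM pool exhausted: assign every NREM epoch to a distinct REM epoch
    pm <- assign_min_distance(nrem_idx, rem_idx)[, 2:1, drop = FALSE]
    unmatched <- setdiff(rem_idx, pm[, 1])
    warning(length(unmatched), " REM epoch(s) left unmatched: NREM pool exhausted")
  }
  pairs_df <- data.frame(rem_epoch = pm[, 1], nrem_epoch = pm[, 2],
                         distance_min = abs(pm[, 1] - pm[, 2]) * 0.5)
  pairs_df <- pairs_df[order(pairs_df$rem_epoch), , drop = FALSE]
  rownames(pairs_df) <- NULL
  structure(list(pairs = pairs_df,
                 mean_distance_min = mean(pairs_df$distance_min),
                 unmatched_rem = unmatched),
            class = "epoch_pairing")
}

#' @export
print.epoch_pairing <- function(x, ...) {
  cat(sprintf("<epoch_pairing> %d REM-NREM pairs, mean distance %.1f min",
              nrow(x$pairs), x$mean_distance_min))
  if (length(x$unmatched_rem))
    cat(sprintf(" (%d REM unmatched)", length(x$unmatched_rem)))
  cat("\n")
  invisible(x)
}

#' @rdname match_rem_nrem
#' @param pairing an `epoch_pairing`.
#' @param path CSV output path (`rem_epoch,nrem_epoch,distance_min`).
#' @export
write_pairing_csv <- function(pairing, path) {
  utils::write.csv(pairing$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Prepare a hypnogram for analysis
#'
#' Convenience wrapper chaining scorer consensus (skipped in single-scorer
#' mode), isolated-epoch dropping and REM-NREM matching, with per-stage
#' bookkeeping of how many epochs each step removed.
#'
#' @param h1 primary hypnogram.
#' @param h2 optional second scorer's hypnogram.
#' @return list: `eligible` mask, `pairing`, and `bookkeeping` (total,
#'   consistent, dropped_isolated counts).
#' @export
prepare_hypnogram <- function(h1, h2 = NULL) {
  n <- length(h1$stages)
  if (is.null(h2)) {
    elig <- rep(TRUE, n); frac <- NA_real_
  } else {
    cm <- consensus_mask(h1, h2)
    elig <- cm$mask; frac <- cm$consistent_fraction
  }
  n_consistent <- sum(elig)
  elig2 <- drop_isolated(h1, elig)
  pairing <- match_rem_nrem(h1, elig2)
  list(eligible = elig2, pairing = pairing,
       bookkeeping = list(total = n, consistent = n_consistent,
                          consistent_fraction = frac,
                          dropped_isolated = n_consistent - sum(elig2),
                          n_pairs = nrow(pairing$pairs)))
}
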