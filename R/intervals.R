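# Half-open time-interval utilities ([start, end), seconds).

# Merge overlapping/adjacent intervals; m is a 2-column matrix (start, end).
merge_intervals <- function(m) {
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (j in seq_len(nrow(m))[-1]) {
    if (m[j, 1] <= out[nrow(out), 2] + 1e-12) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[j, 2])
    } else out <- rbind(out, m[j, , drop = FALSE])
  }
  out
}

interval_total_length <- function(m) {
  if (!nrow(m)) return(0)
  m <- merge_intervals(m)
  sum(m[, 2] - m[, 1])
}

interval_intersection <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), ncol = 2))
  a <- merge_intervals(a); b <- merge_intervals(b)
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a[i, 1], b[j, 1]); e <- min(a[i, 2], b[j, 2])
    if (e > s) out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

#' Jaccard overlap of two interval sets
#'
#' Ratio of the total length of the intersection to that of the union of two
#' sets of half-open time intervals; used to score recovery of ground-truth
#' loss-of-atonia or burst intervals.
#'
#' @param a,b two-column matrices (start, end) in seconds.
#' @return scalar in [0, 1]; 1 for identical coverage, NA if both are empty.
#' @export
interval_jaccard <- function(a, b) {
  ia <- interval_total_length(a); ib <- interval_total_length(b)
  if (ia == 0 && ib == 0) return(NA_real_)
  inter <- interval_total_length(interval_intersection(a, b))
  inter / (ia + ib - inter)
}
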