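# Group-level nonparametric comparisons and clinical-score correlations on
# cohort feature tables (one row per subject).

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test for within-subject comparisons (integrated
#' EMG, beta power, burst duration, Granger values).  Zero differences are
#' dropped (the classical convention); if all differences are zero the test
#' is degenerate and reported as such with p = 1.  Exact null distribution
#' for n <= 25 without ties, normal approximation with correction otherwise.
#'
#' @param a,b paired per-subject values (equal length >= 5).
#' @return list: `statistic` (V), `p`, `n_effective`, `degenerate`.
#' @export
paired_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p = 1, n_effective = 0L,
                degenerate = TRUE))
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null by convolution over the (tie-averaged) ranks; doubling makes
    # every rank an integer so the distribution lives on a lattice
    r2 <- as.integer(round(2 * r))
    pmf <- c(1)                        # distribution of 2V under the null
    for (rk in r2) pmf <- (c(pmf, numeric(rk)) + c(numeric(rk), pmf)) / 2
    v2 <- as.integer(round(2 * v))
    p_le <- sum(pmf[seq_len(v2 + 1)])
    p_ge <- sum(pmf[(v2 + 1):length(pmf)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    w <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    p <- w$p.value
  }
  list(statistic = v, p = p, n_effective = n, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-tailed unpaired rank-sum comparison (e.g. RSWA%, envelope correlation
#' between PD and dystonia groups); exact null when feasible, tie-corrected
#' normal approximation otherwise.
#'
#' @param a,b independent samples (each >= 3 values).
#' @return list: `statistic` (U), `p`.
#' @export
unpaired_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  if (length(a) < 3 || length(b) < 3) stop("each sample needs >= 3 values")
  exact <- (length(a) + length(b)) <= 50 && !any(duplicated(c(a, b)))
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Kruskal-Wallis test across groups
#'
#' @param groups list of numeric vectors (one per group, each non-empty).
#' @return list: `statistic` (H), `p`, `df`.
#' @export
group_kruskal <- function(groups) {
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  k <- stats::kruskal.test(groups)
  list(statistic = unname(k$statistic), p = k$p.value,
       df = unname(k$parameter))
}

#' Spearman correlation of a feature with a clinical score
#'
#' @param features data.frame of subject features (needs columns `x`, `y`,
#'   and `group` when `subset_group` is given).
#' @param x,y column names to correlate.
#' @param subset_group optional group label(s) to restrict to.
#' @return list: `rho`, `p`, `n`; `rho` is NA with a message when a column is
#'   constant (undefined ranks).
#' @export
clinical_correlation <- function(features, x, y, subset_group = NULL) {
  d <- features
  if (!is.null(subset_group)) d <- d[d$group %in% subset_group, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c(x, y)]), , drop = FALSE]
  if (nrow(d) < 5) stop("need >= 5 subjects after subsetting")
  if (stats::sd(d[[x]]) == 0 || stats::sd(d[[y]]) == 0) {
    message("constant column: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(d)))
  }
  ct <- suppressWarnings(stats::cor.test(d[[x]], d[[y]], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' Dichotomize subjects into clinical RBD vs non-RBD
#'
#' Clinically diagnosed RBD is taken as an RBD screening questionnaire score
#' (RBDSQ) of at least 5.
#'
#' @param features data.frame with an `rbdsq` column.
#' @return list of logical masks `rbd` and `nrbd`; subjects with missing
#'   scores are excluded from both with a warning.
#' @export
dichotomize_rbd <- function(features) {
  if (!"rbdsq" %in% names(features)) stop("features need an rbdsq column")
  s <- features$rbdsq
  if (anyNA(s))
    warning(sum(is.na(s)), " subject(s) with missing RBDSQ excluded")
  list(rbd = !is.na(s) & s >= 5, nrbd = !is.na(s) & s < 5)
}

#' Benjamini-Hochberg adjustment (optional sensitivity analysis)
#'
#' The primary reporting applies no multiple-testing correction; this helper
#' adjusts a results table's p-values for sensitivity analyses.
#'
#' @param results data.frame with a `p` column.
#' @return the table with an added `p_adj` column.
#' @export
adjust_results_bh <- function(results) {
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  results
}
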