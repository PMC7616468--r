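test_that("consensus mask marks epochs where both scorers agree", {
  h <- hypnogram(c("R", "R", "N2"))
  cm <- consensus_mask(h, h)
  expect_true(all(cm$mask))
  expect_equal(cm$consistent_fraction, 1)

  h2 <- hypnogram(c("R", "N2", "N2"))
  cm2 <- consensus_mask(h, h2)
  expect_equal(cm2$mask, c(TRUE, FALSE, TRUE))
  expect_equal(cm2$consistent_fraction, 2 / 3)

  expect_error(consensus_mask(h, hypnogram(c("R", "R"))), "length")
})

test_that("a corrupting second scorer yields the expected consistent fraction", {
  set.seed(1)
  stages <- sample(c("W", "N1", "N2", "N3", "R"), 1000, replace = TRUE)
  s2 <- rembeta:::corrupt_hypnogram(stages, 0.128)
  cm <- consensus_mask(hypnogram(stages), hypnogram(s2))
  expect_equal(cm$consistent_fraction, 1 - 0.128, tolerance = 0.001)
})

test_that("isolated epochs are dropped, boundaries by single-neighbour rule", {
  drop1 <- function(stages) which(!drop_isolated(hypnogram(stages))) - 1L
  # the single N2 between two REM epochs is isolated; under the boundary
  # convention the flanking single-epoch REM runs fall as well
  expect_true(1L %in% drop1(c("R", "N2", "R")))
  expect_equal(drop1(c("R", "R", "N2", "R", "R")), 2L)
  expect_equal(drop1(c("N2", "N2", "N2")), integer(0))
  expect_equal(drop1(c("R", "R", "N2", "N2", "R", "N2", "N2")), 4L)
  # boundary epochs compared only to the single neighbour
  expect_equal(drop1(c("W", "N2", "N2")), 0L)
  # existing ineligibility is preserved
  h <- hypnogram(c("N2", "N2", "N2"))
  expect_equal(drop_isolated(h, c(TRUE, FALSE, TRUE)), c(TRUE, FALSE, TRUE))
})

test_that("REM-NREM matching is a nearest-neighbour bijection without replacement", {
  h <- hypnogram(c("N2", "R"))
  p <- match_rem_nrem(h)
  expect_equal(p$pairs$rem_epoch, 1)
  expect_equal(p$pairs$nrem_epoch, 0)
  expect_equal(p$mean_distance_min, 0.5)

  p2 <- match_rem_nrem(hypnogram(c("N2", "R", "R", "N2")))
  expect_equal(p2$pairs[order(p2$pairs$rem_epoch), c("rem_epoch", "nrem_epoch")],
               data.frame(rem_epoch = c(1, 2), nrem_epoch = c(0, 3)),
               ignore_attr = TRUE)

  expect_error(match_rem_nrem(hypnogram(c("W", "W", "R"))), "NREM")
  expect_warning(match_rem_nrem(hypnogram(c("R", "R", "N2"))), "unmatched")
})

test_that("greedy matching equals the brute-force minimum-distance assignment", {
  brute_total <- function(rem, nrem) {
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(r) c(v[i], r))))
    best <- Inf
    for (cmb in utils::combn(length(nrem), length(rem), simplify = FALSE))
      for (pp in perms(seq_along(cmb)))
        best <- min(best, sum(abs(rem - nrem[cmb][pp])))
    best
  }
  set.seed(7)
  tested <- 0
  for (i in 1:60) {
    runs <- data.frame(
      stage = sample(c("W", "N1", "N2", "N3", "R"), sample(3:6, 1), replace = TRUE),
      n = sample(1:4, sample(3:6, 1), replace = TRUE)[1])
    h <- hypnogram(rep(runs$stage, pmax(runs$n, 1)))
    elig <- drop_isolated(h)
    rem <- which(h$stages == "R" & elig) - 1L
    nrem <- which(h$stages %in% c("N1", "N2", "N3") & elig) - 1L
    if (!length(rem) || length(rem) > 5 || length(rem) > length(nrem)) next
    tested <- tested + 1
    g <- match_rem_nrem(h, elig)
    expect_equal(sum(abs(g$pairs$rem_epoch - g$pairs$nrem_epoch)),
                 brute_total(rem, nrem))
    # bijection invariants
    expect_true(all(h$stages[g$pairs$rem_epoch + 1] == "R"))
    expect_true(all(h$stages[g$pairs$nrem_epoch + 1] %in% c("N1", "N2", "N3")))
    expect_false(any(duplicated(g$pairs$nrem_epoch)))
  }
  expect_gte(tested, 10)
})

test_that("hypnogram CSV round-trips", {
  h <- hypnogram(c("W", "N1", "N2", "N3", "R"))
  f <- tempfile(fileext = ".csv")
  write_hypnogram_csv(h, f)
  expect_equal(read_hypnogram_csv(f)$stages, h$stages)
  expect_error(hypnogram(c("N2", "REM")), "unknown stage")
})
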