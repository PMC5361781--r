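const_table <- function() {
  m <- matrix(rep(c(0.5, 0.3, 0.2), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  abundance_table(m, times = 0:3, is_relative = TRUE)
}

test_that("constant composition gives constant rank columns", {
  rm_ <- rank_over_time(const_table(), top_n = 3)
  expect_true(all(rm_$ranks == matrix(1:3, 3, 4)))
  expect_equal(rm_$taxon_ids, c("a", "b", "c"))
})

test_that("ties go to the more dominant taxon, then lexicographic ID", {
  m <- rbind(a = c(0.5, 0.4, 0.5), b = c(0.3, 0.4, 0.3), c = c(0.2, 0.2, 0.2))
  tab <- abundance_table(m, times = 0:2, is_relative = TRUE)
  rm_ <- rank_over_time(tab, top_n = 3)
  # at t = 1 a and b tie at 0.4; a has the better overall rank
  expect_equal(rm_$ranks[, 2], c(a = 1L, b = 2L, c = 3L))
})

test_that("an abundance swap swaps ranks exactly at that timepoint", {
  m <- rbind(a = c(0.55, 0.15, 0.55), b = c(0.3, 0.3, 0.3),
             c = c(0.15, 0.55, 0.15))
  tab <- abundance_table(m, times = 0:2, is_relative = TRUE)
  rm_ <- rank_over_time(tab, top_n = 3)
  expect_equal(unname(rm_$ranks[, 1]), c(1L, 2L, 3L))
  expect_equal(unname(rm_$ranks[, 2]), c(3L, 2L, 1L))
  expect_equal(unname(rm_$ranks[, 3]), c(1L, 2L, 3L))
})

test_that("every rank column is a permutation, even with absent taxa", {
  set.seed(9)
  m <- matrix(runif(30 * 12), nrow = 30)
  m[sample(length(m), 80)] <- 0   # plenty of absences
  m <- sweep(m + 1e-12, 2, colSums(m + 1e-12), "/")
  rownames(m) <- sprintf("g%02d", 1:30)
  tab <- abundance_table(m, times = 0:11, is_relative = TRUE)
  rm_ <- rank_over_time(tab, top_n = 20)
  for (k in seq_len(rm_$t)) {
    expect_setequal(rm_$ranks[, k], 1:20)
  }
})

test_that("RSI limit cases and hand case are exact", {
  expect_identical(rsi(rep(5, 30), N = 20), 1)
  expect_identical(rsi(rep(c(1, 20), 15), N = 20), 0)
  expect_equal(rsi(c(1, 2, 2), N = 3), (1 - 1 / 4)^4)
  expect_equal(rsi(c(1, 2, 2), N = 3), 0.31640625)
  expect_error(rsi(1, N = 3), "at least 2")
})

test_that("one extra rank hop never increases the RSI", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(5:15, 1)
    t <- sample(5:20, 1)
    r <- sample(N, t, replace = TRUE)
    base <- rsi(r, N = N)
    k <- sample(t, 1)
    r2 <- r
    r2[k] <- if (r[k] < N) r[k] + 1L else r[k] - 1L
    # adding one unit of displacement somewhere cannot raise RSI above the
    # one-hop-removed bound
    d_base <- sum(abs(diff(r)))
    d_new <- sum(abs(diff(r2)))
    if (d_new >= d_base) expect_lte(rsi(r2, N = N), base)
  }
})

test_that("RV is the mean deviation from the overall order", {
  rm_ <- rank_over_time(const_table(), top_n = 3)
  expect_equal(rank_variability(rm_), rep(0, 4))
  # swap the top two taxa at one timepoint of a 10-taxon fixture
  m <- matrix(rep(seq(0.19, 0.01, by = -0.02), 3), nrow = 10)
  m[1:2, 2] <- m[2:1, 2]
  rownames(m) <- letters[1:10]
  tab <- abundance_table(m, times = 0:2, is_relative = FALSE)
  tab <- to_relative(tab)
  rm2 <- rank_over_time(tab, top_n = 10)
  expect_equal(rank_variability(rm2), c(0, 0.2, 0))
})

test_that("RV of a full rank reversal matches brute-force summation", {
  N <- 9
  m <- matrix(rep(seq(N, 1) / sum(1:N), 3), nrow = N)
  m[, 2] <- rev(m[, 2])
  rownames(m) <- letters[1:N]
  tab <- abundance_table(m, times = 0:2, is_relative = TRUE)
  rv <- rank_variability(rank_over_time(tab, top_n = N))
  oracle <- mean(abs(seq_len(N) - (N + 1 - seq_len(N))))
  expect_equal(rv[2], oracle)
})

test_that("DV measures consecutive-rank displacement", {
  rm_ <- rank_over_time(const_table(), top_n = 3)
  dv <- difference_variability(rm_)
  expect_true(is.na(dv[1]))
  expect_equal(dv[-1], rep(0, 3))
  # single adjacent swap between consecutive samples, N = 10
  m <- matrix(rep(seq(0.19, 0.01, by = -0.02), 3), nrow = 10)
  m[1:2, 2] <- m[2:1, 2]
  rownames(m) <- letters[1:10]
  tab <- to_relative(abundance_table(m, times = 0:2))
  dv2 <- difference_variability(rank_over_time(tab, top_n = 10))
  expect_equal(dv2[-1], c(0.2, 0.2))
  # when the previous column equals the overall order, DV(k) = RV(k)
  rm3 <- rank_over_time(tab, top_n = 10)
  expect_equal(dv2[2], rank_variability(rm3)[2])
})

test_that("stability islands flag mid-rank taxa that out-stabilize dominants", {
  # constructed report: 15 taxa; taxon at overall rank 12 has RSI 0.9 amid
  # dominant taxa at 0.3
  rep_ <- structure(list(
    rsi = tibble::tibble(taxon_id = sprintf("g%02d", 1:15),
                         overall_rank = 1:15,
                         rsi = c(rep(0.3, 11), 0.9, rep(0.2, 3))),
    variability = NULL, N = 15, t = 10, p = 4), class = "rank_report")
  expect_equal(stability_islands(rep_, rank_band = 11:14), "g12")
  # nothing above threshold -> empty
  rep_lo <- rep_
  rep_lo$rsi$rsi <- rep(0.1, 15)
  expect_length(stability_islands(rep_lo), 0)
  # a dominant (rank 1) taxon is outside the band even with high RSI
  rep_dom <- rep_
  rep_dom$rsi$rsi <- c(0.99, rep(0.3, 14))
  expect_length(stability_islands(rep_dom, rank_band = 11:14), 0)
})

test_that("ordered-phase dynamics make dominant taxa more rank-stable", {
  cohort <- gen_langevin_cohort(n_subjects = 1, n_taxa = 45,
                                n_timepoints = 25, V = 0.03,
                                F_range = c(0.5, 8), depth = NULL,
                                burn_in = 5, steps_per_day = 100, seed = 42)
  rm_ <- rank_over_time(cohort[[1]], top_n = 40)
  rep_ <- rank_report(rm_)
  top5 <- mean(rep_$rsi$rsi[rep_$rsi$overall_rank <= 5])
  mid <- mean(rep_$rsi$rsi[rep_$rsi$overall_rank %in% 20:40])
  expect_gt(top5, mid)
})
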