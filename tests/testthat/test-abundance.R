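test_that("TSV round trip preserves counts, times, and labels", {
  m <- matrix(c(2, 3, 5, 4, 4, 2, 1, 1, 1, 2, 3, 4), nrow = 3,
              dimnames = list(c("g_A", "g_B", "g_C"), NULL))
  paths <- write_fixture_tsv(m, days = c(0, 3, 7, 10))
  tab <- read_taxa_table(paths$taxa, paths$meta)
  expect_s3_class(tab, "abundance_table")
  expect_equal(tab$times, c(0, 3, 7, 10))
  expect_equal(unname(tab$counts), unname(m))
  expect_equal(tab$taxon_ids, c("g_A", "g_B", "g_C"))
  expect_equal(tab$subject_id, "S1")

  # write_taxa_table is the inverse
  dir <- withr::local_tempdir()
  out_taxa <- file.path(dir, "out.tsv")
  out_meta <- file.path(dir, "out_meta.tsv")
  write_taxa_table(tab, out_taxa, out_meta)
  tab2 <- read_taxa_table(out_taxa, out_meta)
  expect_equal(tab2$counts, tab$counts)
  expect_equal(tab2$times, tab$times)
})

test_that("series shorter than three timepoints are rejected", {
  m <- matrix(1:6, nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(abundance_table(m, times = c(0, 1)), "insufficient series")
  paths <- write_fixture_tsv(m, days = c(0, 5))
  expect_error(read_taxa_table(paths$taxa, paths$meta), "insufficient series")
})

test_that("invalid inputs fail validation with informative errors", {
  m <- matrix(c(1, 2, -3, 4, 5, 6), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  expect_error(abundance_table(m, times = 0:2), "negative")
  m2 <- matrix(1:6, nrow = 2, dimnames = list(c("a", "b"), NULL))
  expect_error(abundance_table(m2, times = c(0, 1, 1)), "duplicate")
  # metadata missing a day names the sample
  m3 <- matrix(1:9, nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  paths <- write_fixture_tsv(m3, days = c(0, 2, 4))
  meta <- readr::read_tsv(paths$meta, show_col_types = FALSE)
  meta$day[2] <- NA
  expect_error(read_taxa_table(paths$taxa, meta), "S1_02")
})

test_that("unsorted sample times are sorted on construction", {
  m <- matrix(1:8, nrow = 2, dimnames = list(c("a", "b"), NULL))
  tab <- abundance_table(m, times = c(3, 0, 7, 1),
                         interval_labels = c("x", "h", "y", "h"))
  expect_equal(tab$times, c(0, 1, 3, 7))
  expect_equal(tab$interval_labels, c("h", "h", "x", "y"))
  expect_equal(unname(tab$counts[, 1]), c(3, 4))  # column from time 0
})

test_that("to_relative divides by column totals and is one-shot", {
  m <- matrix(c(2, 3, 5, 1, 1, 2, 4, 4, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  tab <- abundance_table(m, times = 0:2)
  rel <- to_relative(tab)
  expect_true(rel$is_relative)
  expect_equal(unname(rel$counts[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(rel$counts)), rep(1, 3))
  expect_error(to_relative(rel), "already relative")

  m0 <- m; m0[, 2] <- 0
  expect_error(to_relative(abundance_table(m0, times = 0:2)), "zero-total")
})

test_that("compute_stats matches hand-computed mean, sd, sem", {
  m <- make_relative_matrix(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3))
  tab <- make_table(m)
  st <- compute_stats(tab, min_nonzero = 2, check_relative = FALSE)
  expect_equal(st$mean, c(0.1, 0.2))
  expect_equal(st$sd, c(0, 0.1))
  expect_equal(st$sem, c(0, 0.1 / sqrt(3)))
  expect_equal(st$n, c(3L, 3L))
})

test_that("rare taxa are filtered by min_nonzero and empty results error", {
  m <- make_relative_matrix(c(0.5, rep(0, 9)), rep(0.1, 10))
  tab <- make_table(m)
  st <- compute_stats(tab, min_nonzero = 2, check_relative = FALSE)
  expect_equal(st$taxon_id, "g_02")
  expect_error(compute_stats(tab, min_nonzero = 11, check_relative = FALSE),
               "filtered")
})

test_that("temporal statistics are invariant to timepoint permutation and sem <= sd", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(6 * 8), nrow = 6,
                dimnames = list(sprintf("t%02d", 1:6), NULL))
    tab <- make_table(m)
    st1 <- compute_stats(tab, check_relative = FALSE)
    perm <- sample(8)
    st2 <- compute_stats(tab, timepoints = perm, check_relative = FALSE)
    expect_equal(st1$mean, st2$mean)
    expect_equal(st1$sd, st2$sd)
    expect_true(all(st1$sem <= st1$sd + 1e-15))
  }
})

test_that("interval subsetting extracts a labelled state", {
  m <- matrix(runif(12), nrow = 2, dimnames = list(c("a", "b"), NULL))
  tab <- abundance_table(m, times = 0:5,
                         interval_labels = c("healthy", "healthy", "healthy",
                                             "abx", "abx", "abx"))
  sub <- subset_interval(tab, "abx")
  expect_equal(sub$times, 3:5)
  expect_equal(unname(sub$counts), unname(m[, 4:6]))
  expect_error(subset_interval(tab, "missing"), "insufficient series")
})

test_that("as_tibble produces the long form", {
  m <- matrix(1:6, nrow = 2, dimnames = list(c("a", "b"), NULL))
  tab <- abundance_table(m, times = c(0, 2, 5))
  long <- tibble::as_tibble(tab)
  expect_equal(nrow(long), 6)
  expect_equal(long$abundance[long$taxon_id == "a" & long$time == 2], 3)
})
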