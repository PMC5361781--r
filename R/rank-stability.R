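#' Rank-over-time matrix of the dominant taxa
#'
#' Orders taxa by their accumulated relative abundance over the whole series
#' (the overall rank), keeps the `top_n` most dominant, and ranks that fixed
#' set at every timepoint (rank 1 = most abundant). Ties are broken by
#' overall rank, then lexicographic taxon ID, so results are reproducible.
#'
#' @param table A relative [abundance_table()].
#' @param top_n Number of dominant taxa to track (default 50, capped at the
#'   number of taxa).
#' @return Object of class `rank_matrix`: list with `ranks` (taxa x
#'   timepoint integer matrix, rows ordered by overall rank), `times`,
#'   `overall_rank`, `N`, `t`. A taxon absent (zero) at a timepoint takes
#'   the worst ranks within the tracked set, tie-broken like any other tie,
#'   so every column stays a permutation of 1..N.
#' @export
rank_over_time <- function(table, top_n = 50L) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$is_relative) stop("table must be relative", call. = FALSE)
  if (top_n < 2L) stop("top_n must be >= 2", call. = FALSE)
  top_n <- min(top_n, nrow(table$counts))

  acc <- rowSums(table$counts)
  overall_ord <- order(-acc, table$taxon_ids)
  sel <- overall_ord[seq_len(top_n)]
  m <- table$counts[sel, , drop = FALSE]
  # rows now sorted by overall rank: overall_rank = row index
  n_t <- ncol(m)
  ranks <- matrix(NA_integer_, nrow = top_n, ncol = n_t,
                  dimnames = list(rownames(m), NULL))
  for (k in seq_len(n_t)) {
    v <- m[, k]
    # order by abundance desc, ties by overall rank (row index), then ID
    ord <- order(-v, seq_len(top_n))
    ranks[ord, k] <- seq_len(top_n)
  }
  structure(
    list(ranks = ranks, times = table$times, taxon_ids = rownames(m),
         overall_rank = seq_len(top_n), N = top_n, t = n_t,
         subject_id = table$subject_id),
    class = "rank_matrix"
  )
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat("<rank_matrix>", x$N, "taxa x", x$t, "timepoints (subject",
      x$subject_id, ")\n")
  invisible(x)
}

#' @method as_tibble rank_matrix
#' @export
as_tibble.rank_matrix <- function(x, ...) {
  tibble::tibble(
    taxon_id = rep(x$taxon_ids, times = x$t),
    overall_rank = rep(x$overall_rank, times = x$t),
    time = rep(x$times, each = x$N),
    rank = as.vector(x$ranks)
  )
}

#' Rank stability index of one rank series
#'
#' `RSI = (1 - D / ((N - 1)(t - 1)))^p`, where `D` is the cumulative
#' absolute rank displacement of the taxon over consecutive timepoints
#' ("true rank hops") and `(N - 1)(t - 1)` the maximum attainable by
#' oscillating between the extreme ranks. RSI is exactly 1 for a taxon
#' whose rank never changes and exactly 0 for extreme oscillation; the
#' power `p = 4` stretches resolution in the stable region.
#'
#' @param ranks Integer rank series of one taxon (values in 1..N).
#' @param N Number of ranked taxa.
#' @param t Number of timepoints; defaults to `length(ranks)`.
#' @param p Power index (default 4).
#' @return The RSI, in \[0, 1\].
#' @examples
#' rsi(c(1, 2, 2), N = 3)          # (1 - 1/4)^4
#' rsi(rep(5, 30), N = 20)         # 1
#' @export
rsi <- function(ranks, N, t = length(ranks), p = 4) {
  if (t < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (N < 2L) stop("N must be >= 2", call. = FALSE)
  if (any(ranks < 1 | ranks > N)) stop("ranks must lie in 1..N", call. = FALSE)
  D <- sum(abs(diff(ranks)))
  (1 - D / ((N - 1) * (t - 1)))^p
}

#' Per-timepoint rank variability (RV)
#'
#' Mean absolute difference between every tracked taxon's rank at a
#' timepoint and its overall (accumulated-abundance) rank.
#'
#' @param matrix A [rank_over_time()] result.
#' @return Numeric vector, one RV per timepoint.
#' @export
rank_variability <- function(matrix) {
  stopifnot(inherits(matrix, "rank_matrix"))
  colMeans(abs(matrix$ranks - matrix$overall_rank))
}

#' Per-timepoint difference variability (DV)
#'
#' Mean absolute difference between every tracked taxon's rank at a
#' timepoint and its rank at the previous sampling point; undefined (NA)
#' at the first timepoint.
#'
#' @inheritParams rank_variability
#' @return Numeric vector, one DV per timepoint (first is NA).
#' @export
difference_variability <- function(matrix) {
  stopifnot(inherits(matrix, "rank_matrix"))
  if (matrix$t < 2L) stop("need at least 2 timepoints", call. = FALSE)
  dv <- colMeans(abs(matrix$ranks[, -1, drop = FALSE] -
                       matrix$ranks[, -matrix$t, drop = FALSE]))
  c(NA_real_, dv)
}

#' Full rank-stability report
#'
#' Computes per-taxon RSI and per-timepoint RV/DV for a rank matrix.
#'
#' @inheritParams rank_variability
#' @param p RSI power index (default 4).
#' @return Object of class `rank_report`: list with `rsi` (tibble
#'   `taxon_id`, `overall_rank`, `rsi`), `variability` (tibble `time`,
#'   `rv`, `dv`), and the inputs `N`, `t`, `p`.
#' @export
rank_report <- function(matrix, p = 4) {
  stopifnot(inherits(matrix, "rank_matrix"))
  rsi_vals <- apply(matrix$ranks, 1, rsi, N = matrix$N, t = matrix$t, p = p)
  structure(
    list(
      rsi = tibble::tibble(taxon_id = matrix$taxon_ids,
                           overall_rank = matrix$overall_rank,
                           rsi = unname(rsi_vals)),
      variability = tibble::tibble(time = matrix$times,
                                   rv = rank_variability(matrix),
                                   dv = difference_variability(matrix)),
      N = matrix$N, t = matrix$t, p = p
    ),
    class = "rank_report"
  )
}

#' @export
print.rank_report <- function(x, ...) {
  cat("<rank_report>", x$N, "taxa x", x$t, "timepoints, p =", x$p, "\n")
  cat("  mean RSI =", signif(mean(x$rsi$rsi), 4),
      "| mean RV =", signif(mean(x$variability$rv), 4),
      "| mean DV =", signif(mean(x$variability$dv, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' @rdname rank_report
#' @param x A `rank_report`.
#' @param ... Unused.
#' @method tidy rank_report
#' @export
tidy.rank_report <- function(x, ...) x$rsi

#' Rank stability islands
#'
#' Medium-ranked taxa that are markedly more rank-stable than their
#' dominance warrants: taxa whose overall rank lies in `rank_band`, whose
#' RSI is at least `rsi_threshold`, and whose RSI exceeds that of at least
#' one more-dominant taxon.
#'
#' @param report A [rank_report()].
#' @param rsi_threshold Minimum RSI (default 0.70).
#' @param rank_band Integer range of overall ranks eligible (default
#'   11..40).
#' @return Character vector of flagged taxon IDs.
#' @export
stability_islands <- function(report, rsi_threshold = 0.70,
                              rank_band = 11:40) {
  stopifnot(inherits(report, "rank_report"))
  df <- report$rsi
  flagged <- character(0)
  for (i in seq_len(nrow(df))) {
    r <- df$overall_rank[i]
    if (!(r %in% rank_band)) next
    if (df$rsi[i] < rsi_threshold) next
    better <- df$rsi[df$overall_rank < r]
    if (length(better) > 0 && any(df$rsi[i] > better)) {
      flagged <- c(flagged, df$taxon_id[i])
    }
  }
  flagged
}

#' Plot a rank matrix with its RSI sidebar
#'
#' Heat-map style rank-over-time panel (taxa ordered by overall dominance)
#' with per-taxon RSI shown on the right.
#'
#' @param object A `rank_matrix`.
#' @param p RSI power for the sidebar.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rank_matrix
#' @export
autoplot.rank_matrix <- function(object, p = 4, ...) {
  long <- tibble::as_tibble(object)
  rep_ <- rank_report(object, p = p)
  long <- dplyr::left_join(long, rep_$rsi, by = c("taxon_id", "overall_rank"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time,
                               y = stats::reorder(.data$taxon_id,
                                                  -.data$overall_rank),
                               fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "time (days)", y = NULL, fill = "rank",
                  title = "Rank variation over time (most dominant at top)")
}
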