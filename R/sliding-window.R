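#' Time course of Taylor parameters via sliding windows
#'
#' Splits the series into overlapping windows of `window_size` consecutive
#' timepoints (each next window adds the next sampling time and drops the
#' earliest one), fits Taylor's law within every window, and reports each
#' window's parameters against the mean sampling time of the window. This
#' is how slow drifts and acute perturbations (antibiotics, infections)
#' show up as transient rises of `V(t)`.
#'
#' @param table A relative [abundance_table()].
#' @param window_size Number of timepoints per window (default 5, minimum
#'   3).
#' @param n_replicates Bootstrap replicates per window fit (default 200,
#'   fewer than the global default since each window has few points).
#' @param seed Integer seed shared by the window fits.
#' @param min_nonzero Per-window taxon filter (see [compute_stats()]);
#'   taxa constant within a window are additionally dropped by the log-log
#'   fit.
#' @param check_relative Passed to [compute_stats()]; set `FALSE` for
#'   tables holding proportions that must not be re-closed.
#' @param ... Passed to [fit_taylor_xweighted()].
#'
#' @return A `window_series` tibble: one row per window with `window`,
#'   `time` (mean sampling time), `V`, `err_V`, `beta`, `err_beta`, `r2`,
#'   `n_taxa`. Windows whose fit fails are kept as rows of NA.
#' @examples
#' tab <- gen_exact_taylor(V = 0.05, beta = 0.75, n_timepoints = 12, seed = 2)
#' sliding_taylor(tab, window_size = 5, seed = 1)
#' @export
sliding_taylor <- function(table, window_size = 5L, n_replicates = 200L,
                           seed = NULL, min_nonzero = 2L,
                           check_relative = TRUE, ...) {
  stopifnot(inherits(table, "abundance_table"))
  if (check_relative && !table$is_relative) {
    stop("table must be relative", call. = FALSE)
  }
  t_n <- length(table$times)
  if (window_size < 3L) stop("window_size must be >= 3", call. = FALSE)
  if (t_n < window_size) {
    stop("series has ", t_n, " timepoints, fewer than window_size = ",
         window_size, call. = FALSE)
  }
  n_win <- t_n - window_size + 1L
  if (!is.null(seed)) set.seed(seed)
  win_seeds <- sample.int(.Machine$integer.max, n_win)

  rows <- purrr::map_dfr(seq_len(n_win), function(w) {
    idx <- w:(w + window_size - 1L)
    res <- try({
      st <- compute_stats(table, min_nonzero = min_nonzero, timepoints = idx,
                          check_relative = check_relative)
      # at window scale the SD sampling noise dominates: debias log(sd) and
      # resample the SDs so the reported errors are realistic
      fit_taylor_xweighted(st, n_replicates = n_replicates,
                           seed = win_seeds[w], debias_sd = TRUE,
                           resample_sd = TRUE, ...)
    }, silent = TRUE)
    base <- tibble::tibble(window = w, time = mean(table$times[idx]))
    if (inherits(res, "try-error")) {
      dplyr::mutate(base, V = NA_real_, err_V = NA_real_, beta = NA_real_,
                    err_beta = NA_real_, r2 = NA_real_, n_taxa = NA_integer_)
    } else {
      dplyr::mutate(base, V = res$V, err_V = res$err_V, beta = res$beta,
                    err_beta = res$err_beta, r2 = res$r2,
                    n_taxa = res$n_taxa)
    }
  })
  class(rows) <- c("window_series", class(rows))
  attr(rows, "window_size") <- window_size
  rows
}

#' Plot the time course of windowed Taylor parameters
#'
#' @param object A `window_series` from [sliding_taylor()].
#' @param parameter `"V"` (default) or `"beta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_series
#' @export
autoplot.window_series <- function(object, parameter = c("V", "beta"), ...) {
  parameter <- match.arg(parameter)
  err_col <- paste0("err_", parameter)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data[[parameter]])) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[parameter]] - .data[[err_col]],
                   ymax = .data[[parameter]] + .data[[err_col]]),
      alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (days)", y = parameter,
                  title = sprintf("Sliding-window %s(t), window = %d points",
                                  parameter, attr(object, "window_size")))
}
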