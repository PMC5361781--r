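#' Fit a single power law SD = V * mean^beta
#'
#' One unweighted power-law fit of temporal standard deviation against
#' temporal mean, either by ordinary least squares on log-transformed data
#' (`mode = "loglog"`, the default: multiplicative scatter around a power law
#' is additive in log space) or by nonlinear least squares on the original
#' scale initialised from the log-log estimate.
#'
#' @param x Numeric vector of per-taxon temporal means (> 0).
#' @param y Numeric vector of per-taxon temporal SDs (same length).
#' @param mode `"loglog"` or `"nonlinear"`.
#' @return A list with `V`, `beta`, `r2`, `cov` (2x2 covariance of
#'   `(log V, beta)` in loglog mode, of `(V, beta)` in nonlinear mode).
#' @export
fit_power_law_single <- function(x, y, mode = c("loglog", "nonlinear")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 points with x > 0 and y > 0", call. = FALSE)
  }
  if (diff(range(x)) == 0) stop("degenerate x: all means equal", call. = FALSE)

  lx <- log(x); ly <- log(y)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  beta <- unname(fit$coefficients[2L])
  logV <- unname(fit$coefficients[1L])
  res <- fit$residuals
  r2_log <- 1 - sum(res^2) / sum((ly - mean(ly))^2)

  if (mode == "loglog") {
    dof <- length(x) - 2L
    s2 <- if (dof > 0) sum(res^2) / dof else 0
    xtx_inv <- chol2inv(chol(crossprod(cbind(1, lx))))
    return(list(V = exp(logV), beta = beta, r2 = r2_log, r2_log = r2_log,
                cov = s2 * xtx_inv, mode = "loglog"))
  }

  nls_fit <- try(minpack.lm::nlsLM(y ~ V * x^b,
                                   start = list(V = exp(logV), b = beta)),
                 silent = TRUE)
  if (inherits(nls_fit, "try-error")) {
    stop("nonlinear power-law fit failed to converge", call. = FALSE)
  }
  cf <- stats::coef(nls_fit)
  resid_lin <- y - cf[["V"]] * x^cf[["b"]]
  r2_lin <- 1 - sum(resid_lin^2) / sum((y - mean(y))^2)
  list(V = unname(cf[["V"]]), beta = unname(cf[["b"]]), r2 = r2_lin,
       r2_log = r2_log, cov = stats::vcov(nls_fit), mode = "nonlinear")
}

new_taylor_fit <- function(V, beta, err_V, err_beta, r2, r2_log, param_corr,
                           n_replicates, converged, fit_mode, n_taxa,
                           replicates = NULL) {
  structure(
    list(V = V, beta = beta, err_V = err_V, err_beta = err_beta,
         r2 = r2, r2_log = r2_log, param_corr = param_corr,
         n_replicates = n_replicates, converged = converged,
         fit_mode = fit_mode, n_taxa = n_taxa, replicates = replicates),
    class = "taylor_fit"
  )
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat("<taylor_fit>", x$fit_mode, "fit on", x$n_taxa, "taxa\n")
  cat(sprintf("  V    = %.4g +/- %.2g\n", x$V, x$err_V))
  cat(sprintf("  beta = %.4g +/- %.2g\n", x$beta, x$err_beta))
  cat(sprintf("  r2 = %.3f | corr(V, beta) = %.3f | replicates = %d%s\n",
              x$r2, x$param_corr, x$n_replicates,
              if (isTRUE(x$converged)) "" else " (tolerance not reached)"))
  invisible(x)
}

#' Taylor's-law fit with x-weighted bootstrap resampling
#'
#' Fits Taylor's power law `sd = V * mean^beta` to per-taxon (mean, SD)
#' pairs, propagating the uncertainty of each mean (its SEM) into the fit.
#' Because the measurement error sits on the independent variable, the fit
#' resamples the mean axis: each replicate perturbs every mean by a Gaussian
#' draw with its SEM as standard deviation (`x*_i = x_i + v_i`,
#' `v_i ~ N(0, SEM_i)`) and refits an unweighted power law; the reported
#' parameters are the replicate means, their uncertainties the replicate
#' standard deviations.
#'
#' Replication stops early once the running means of both `V` and `beta`
#' change by less than `rel_tol` between consecutive checks (every
#' `check_every` replicates, after at least `min_replicates`).
#'
#' @param stats A tibble from [compute_stats()] (columns `mean`, `sd`,
#'   `sem`), or any data frame with those columns.
#' @param n_replicates Maximum number of bootstrap replicates.
#' @param rel_tol Relative-change tolerance for early stopping.
#' @param seed Integer seed; fixes the replicate draws.
#' @param mode Inner fit mode, `"loglog"` (default) or `"nonlinear"`.
#' @param min_replicates,check_every Early-stopping schedule.
#' @param clamp Positive floor applied to resampled means before the log
#'   transform (`"floor"`, default, clamps at 1e-12; `"redraw"` redraws the
#'   perturbation until positive).
#' @param debias_sd Correct the small-sample bias of `log(sd)` (for a
#'   Gaussian sample, `E[log s] - log sigma = (digamma((n-1)/2) -
#'   log((n-1)/2))/2`, a -13.5% bias on `V` at n = 5 but < 1% at n >= 50).
#'   Off by default: the headline fit treats the observed SDs as the
#'   dispersion, and the correction matters only for short windows.
#' @param resample_sd Additionally resample each SD in every replicate from
#'   its own sampling distribution (`s* = s z / exp(2 bias)` with
#'   `z = sqrt(chi2_{n-1}/(n-1))`), so the reported errors include the SD
#'   sampling noise that dominates few-timepoint fits. Off by default (the
#'   x-weighted scheme perturbs only the mean axis); [sliding_taylor()]
#'   turns both corrections on.
#'
#' @return A `taylor_fit` object: `V`, `beta`, `err_V`, `err_beta` (SDs over
#'   replicates), `r2` (replicate mean), `param_corr` (empirical Pearson
#'   correlation of the replicate `(V, beta)` ensemble), `n_replicates`,
#'   `converged`, `fit_mode`. In loglog mode constant taxa (sd = 0) are
#'   excluded; in nonlinear mode they are retained.
#' @seealso [fit_taylor_inversion()] for the deterministic baseline,
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' tab <- gen_poisson_community(10^seq(1, 4, length.out = 30),
#'                              n_timepoints = 50, seed = 1)
#' st <- compute_stats(to_relative(tab))
#' fit_taylor_xweighted(st, seed = 1)
#' @export
fit_taylor_xweighted <- function(stats, n_replicates = 1000L, rel_tol = 1e-3,
                                 seed = NULL, mode = c("loglog", "nonlinear"),
                                 min_replicates = 200L, check_every = 50L,
                                 clamp = c("floor", "redraw"),
                                 debias_sd = FALSE, resample_sd = FALSE) {
  mode <- match.arg(mode)
  clamp <- match.arg(clamp)
  stopifnot(all(c("mean", "sd", "sem") %in% names(stats)))
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if ((debias_sd || resample_sd) && !"n" %in% names(stats)) {
    stop("debias_sd/resample_sd need the per-taxon 'n' column", call. = FALSE)
  }
  x <- stats$mean; y <- stats$sd; sem <- stats$sem
  n_obs <- if ("n" %in% names(stats)) stats$n else rep(NA_integer_, length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(sem))) {
    stop("non-finite values in stats", call. = FALSE)
  }
  if (any(sem < 0)) stop("negative SEMs", call. = FALSE)
  if (mode == "loglog") {
    keep <- y > 0
    x <- x[keep]; y <- y[keep]; sem <- sem[keep]; n_obs <- n_obs[keep]
  }
  if (length(x) < 3L) stop("need at least 3 usable taxa", call. = FALSE)

  log_bias <- 0
  if (debias_sd || resample_sd) {
    log_bias <- 0.5 * (digamma((n_obs - 1) / 2) - log((n_obs - 1) / 2))
  }
  if (debias_sd) y <- y * exp(-log_bias)

  if (!is.null(seed)) set.seed(seed)
  Vs <- numeric(n_replicates)
  betas <- numeric(n_replicates)
  r2s <- numeric(n_replicates)
  n_done <- 0L
  n_failed <- 0L
  converged <- FALSE
  prev_mean <- c(NA_real_, NA_real_)
  floor_x <- 1e-12

  for (r in seq_len(n_replicates)) {
    xs <- x + stats::rnorm(length(x), 0, sem)
    if (clamp == "floor") {
      xs[xs <= 0] <- floor_x
    } else {
      bad <- which(xs <= 0)
      guard <- 0L
      while (length(bad) > 0 && guard < 100L) {
        xs[bad] <- x[bad] + stats::rnorm(length(bad), 0, sem[bad])
        bad <- which(xs <= 0)
        guard <- guard + 1L
      }
      xs[xs <= 0] <- floor_x
    }
    ys <- if (resample_sd) {
      y * sqrt(stats::rchisq(length(y), df = n_obs - 1) / (n_obs - 1)) *
        exp(-log_bias)
    } else {
      y
    }
    f <- try(fit_power_law_single(xs, ys, mode = mode), silent = TRUE)
    if (inherits(f, "try-error")) {
      n_failed <- n_failed + 1L
      next
    }
    n_done <- n_done + 1L
    Vs[n_done] <- f$V; betas[n_done] <- f$beta; r2s[n_done] <- f$r2

    if (n_done >= min_replicates && n_done %% check_every == 0L) {
      cur <- c(mean(Vs[1:n_done]), mean(betas[1:n_done]))
      if (all(is.finite(prev_mean))) {
        rel <- abs(cur - prev_mean) / pmax(abs(prev_mean), .Machine$double.eps)
        if (all(rel < rel_tol)) {
          converged <- TRUE
          break
        }
      }
      prev_mean <- cur
    }
  }
  if (n_done == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  Vs <- Vs[1:n_done]; betas <- betas[1:n_done]; r2s <- r2s[1:n_done]

  err_V <- if (n_done > 1L) stats::sd(Vs) else 0
  err_beta <- if (n_done > 1L) stats::sd(betas) else 0
  pc <- if (n_done > 1L && err_V > 0 && err_beta > 0) {
    stats::cor(Vs, betas)
  } else {
    NA_real_
  }
  new_taylor_fit(V = mean(Vs), beta = mean(betas), err_V = err_V,
                 err_beta = err_beta, r2 = mean(r2s), r2_log = mean(r2s),
                 param_corr = pc, n_replicates = n_done,
                 converged = converged, fit_mode = mode, n_taxa = length(x),
                 replicates = tibble::tibble(V = Vs, beta = betas, r2 = r2s))
}

#' Taylor's-law fit by weighted inversion (deterministic baseline)
#'
#' The classical deterministic treatment of errors on the independent
#' variable: swap the roles of x and y so the uncertainty sits on the
#' dependent variable, run a weighted (1/SEM^2) log-log regression of
#' log(mean) on log(sd), and invert the fitted line algebraically back to
#' `(V, beta)`. Exact on noiseless data; the approximation degrades as the
#' coefficient of determination drops, which is what the bootstrap fit
#' ([fit_taylor_xweighted()]) avoids.
#'
#' @inheritParams fit_taylor_xweighted
#' @param mode Kept for interface symmetry; the inversion is performed in
#'   log space.
#' @return A `taylor_fit` with `n_replicates = 1` and errors propagated from
#'   the weighted-regression covariance.
#' @export
fit_taylor_inversion <- function(stats, mode = c("loglog", "nonlinear")) {
  mode <- match.arg(mode)
  stopifnot(all(c("mean", "sd", "sem") %in% names(stats)))
  x <- stats$mean; y <- stats$sd; sem <- stats$sem
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]; sem <- sem[keep]
  if (length(x) < 3L) stop("need at least 3 usable taxa", call. = FALSE)

  # weights for log(x): var(log x) ~ (sem/x)^2 by the delta method
  w <- (x / pmax(sem, .Machine$double.eps))^2
  lx <- log(x); ly <- log(y)
  # inverted regression: log x = a + b log y, weighted by the x errors
  fit <- stats::lm(lx ~ ly, weights = w)
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  a <- unname(cf[1L]); b <- unname(cf[2L])
  if (b == 0) stop("degenerate inverted slope", call. = FALSE)
  beta <- 1 / b
  logV <- -a / b
  # delta-method propagation through (a, b) -> (logV = -a/b, beta = 1/b)
  J <- matrix(c(-1 / b, a / b^2,
                0, -1 / b^2), nrow = 2, byrow = TRUE)
  vc_out <- J %*% vc %*% t(J)
  V <- exp(logV)
  err_V <- V * sqrt(vc_out[1, 1])
  err_beta <- sqrt(vc_out[2, 2])
  pc <- vc_out[1, 2] / sqrt(vc_out[1, 1] * vc_out[2, 2])
  pred <- logV + beta * lx
  r2 <- 1 - sum((ly - pred)^2) / sum((ly - mean(ly))^2)
  new_taylor_fit(V = V, beta = beta, err_V = err_V, err_beta = err_beta,
                 r2 = r2, r2_log = r2, param_corr = unname(pc),
                 n_replicates = 1L, converged = TRUE, fit_mode = mode,
                 n_taxa = length(x))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Taylor fit
#'
#' @param x A `taylor_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy taylor_fit
#' @export
tidy.taylor_fit <- function(x, ...) {
  tibble::tibble(term = c("V", "beta"),
                 estimate = c(x$V, x$beta),
                 std.error = c(x$err_V, x$err_beta))
}

#' One-row summary of a Taylor fit
#'
#' @param x A `taylor_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the fit parameters and diagnostics.
#' @method glance taylor_fit
#' @export
glance.taylor_fit <- function(x, ...) {
  tibble::tibble(V = x$V, beta = x$beta, err_V = x$err_V,
                 err_beta = x$err_beta, r2 = x$r2, r2_log = x$r2_log,
                 param_corr = x$param_corr, n_replicates = x$n_replicates,
                 converged = x$converged, fit_mode = x$fit_mode,
                 n_taxa = x$n_taxa)
}

#' Plot a Taylor fit over its (mean, SD) cloud
#'
#' Log-log scatter of temporal SD against temporal mean with the fitted
#' power law `sd = V * mean^beta` overlaid.
#'
#' @param object A `taylor_fit`.
#' @param stats The stats tibble the fit was computed from (from
#'   [compute_stats()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot taylor_fit
#' @export
autoplot.taylor_fit <- function(object, stats, ...) {
  stopifnot(all(c("mean", "sd") %in% names(stats)))
  df <- dplyr::filter(stats, .data$mean > 0, .data$sd > 0)
  xr <- range(df$mean)
  line <- tibble::tibble(
    mean = exp(seq(log(xr[1]), log(xr[2]), length.out = 100))
  )
  line$sd <- object$V * line$mean^object$beta
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$sd)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "temporal mean relative abundance",
      y = "temporal SD",
      title = sprintf("Taylor's law: V = %.3g, beta = %.3g (r2 = %.2f)",
                      object$V, object$beta, object$r2)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
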