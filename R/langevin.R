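#' Stationary normalization drift phi0
#'
#' The stationary value of the drift that enforces the compositional
#' constraint `sum(x_i) = 1` in the Langevin community model:
#' `phi0 = (sum_i F_i^(1/(1-alpha)))^(1-alpha)`.
#'
#' @param F Vector of per-taxon fitness values (> 0, units 1/time).
#' @param alpha Drift exponent, `alpha < 1`.
#' @return The scalar `phi0`.
#' @examples
#' phi0(c(1, 1), alpha = 0.5)  # sqrt(2)
#' @export
phi0 <- function(F, alpha) {
  if (alpha >= 1) stop("alpha must be < 1 (systems with alpha >= 1 are unstable)",
                       call. = FALSE)
  if (any(F <= 0)) stop("all fitness values must be > 0", call. = FALSE)
  sum(F^(1 / (1 - alpha)))^(1 - alpha)
}

#' Simulate the Langevin community dynamics
#'
#' Euler-Maruyama integration of the community Langevin equation
#' `dx_i = (F_i x_i^alpha - phi(t) x_i) dt + V x_i^beta dW_i`, where the
#' time-dependent drift `phi(t) = sum_j F_j x_j^alpha dt + sum_j V x_j^beta
#' dW_j` (same noise draws as the diffusion term) keeps `sum(x_i) = 1` at
#' every step. After each step abundances are floored at `x_min` and the
#' composition renormalized.
#'
#' @param F Vector of per-taxon fitness values (> 0).
#' @param V Noise amplitude (>= 0).
#' @param alpha,beta Drift and noise exponents; defaults 0.75.
#' @param x0 Initial composition (positive, sums to 1); default uniform.
#' @param dt Time step; default `1e-3 / max(F)`.
#' @param n_steps Number of integration steps.
#' @param seed Optional integer seed.
#' @param record_every Record the state every this many steps.
#' @param x_min Floor applied to abundances (default 1e-8).
#'
#' @return An object of class `langevin_sim`: list with `x` (taxa x records
#'   matrix of compositions, including the initial state), `times`, and the
#'   parameters.
#' @examples
#' sim <- simulate_langevin(F = rep(1, 5), V = 0.1, n_steps = 2000, seed = 1)
#' colSums(sim$x[, 1:3])
#' @export
simulate_langevin <- function(F, V, alpha = 0.75, beta = 0.75, x0 = NULL,
                              dt = NULL, n_steps = 10000L, seed = NULL,
                              record_every = 10L, x_min = 1e-8) {
  k <- length(F)
  if (any(F <= 0)) stop("all fitness values must be > 0", call. = FALSE)
  if (V < 0) stop("V must be >= 0", call. = FALSE)
  if (is.null(x0)) x0 <- rep(1 / k, k)
  if (length(x0) != k) stop("x0 length must match F", call. = FALSE)
  if (any(x0 <= 0) || abs(sum(x0) - 1) > 1e-9) {
    stop("x0 must be positive and sum to 1", call. = FALSE)
  }
  if (is.null(dt)) dt <- 1e-3 / max(F)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_rec <- floor(n_steps / record_every) + 1L
  out <- matrix(NA_real_, nrow = k, ncol = n_rec)
  rownames(out) <- if (!is.null(names(F))) names(F) else
    sprintf("taxon_%03d", seq_len(k))
  rec_times <- numeric(n_rec)
  x <- x0
  out[, 1L] <- x
  j <- 1L
  sqdt <- sqrt(dt)

  for (step in seq_len(n_steps)) {
    drift <- F * x^alpha
    diff_amp <- V * x^beta
    dW <- stats::rnorm(k, 0, sqdt)
    phi_t <- sum(drift) * dt + sum(diff_amp * dW)
    dx <- drift * dt + diff_amp * dW - x * phi_t
    if (any(!is.finite(dx))) {
      stop("non-finite state at step ", step, call. = FALSE)
    }
    if (any(abs(dx) > 0.5)) {
      stop("step ", step, ": |dx| > 0.5; reduce dt (currently ", dt, ")",
           call. = FALSE)
    }
    x <- x + dx
    x[x < x_min] <- x_min
    x <- x / sum(x)
    if (step %% record_every == 0L) {
      j <- j + 1L
      out[, j] <- x
      rec_times[j] <- step * dt
    }
  }
  structure(
    list(x = out[, 1:j, drop = FALSE], times = rec_times[1:j],
         F = F, V = V, alpha = alpha, beta = beta, dt = dt, x_min = x_min),
    class = "langevin_sim"
  )
}

#' @export
print.langevin_sim <- function(x, ...) {
  cat("<langevin_sim>", nrow(x$x), "taxa,", ncol(x$x), "recorded states to t =",
      signif(max(x$times), 4), "\n")
  cat(sprintf("  alpha = %g, beta = %g, V = %g, dt = %g\n",
              x$alpha, x$beta, x$V, x$dt))
  invisible(x)
}

#' @method as_tibble langevin_sim
#' @export
as_tibble.langevin_sim <- function(x, ...) {
  tibble::tibble(
    taxon_id = rep(rownames(x$x), times = ncol(x$x)),
    time = rep(x$times, each = nrow(x$x)),
    abundance = as.vector(x$x)
  )
}

# d(log P0)/dx has the sign of g(x) = F x^alpha - phi0 x - beta V^2 x^(2 beta - 1)
mode_gradient <- function(x, alpha, beta, F, V, phi0_val) {
  F * x^alpha - phi0_val * x - beta * V^2 * x^(2 * beta - 1)
}

log_density_unnorm <- function(x, alpha, beta, F, V, phi0_val) {
  eq_branch <- abs(2 * beta - (1 + alpha)) < 1e-12
  if (eq_branch) {
    (2 * F / V^2 - 2 * beta) * log(x) -
      (phi0_val / V^2) * x^(2 - 2 * beta) / (1 - beta)
  } else {
    -2 * beta * log(x) +
      (2 * F / V^2) * x^(1 + alpha - 2 * beta) / (1 + alpha - 2 * beta) -
      (phi0_val / V^2) * x^(2 - 2 * beta) / (1 - beta)
  }
}

# interior mode of P0 on (x_min, 1), or NA if none: the log-density derivative
# changes sign with g(x); an interior maximum is a down-crossing of g.
find_interior_mode <- function(alpha, beta, F, V, phi0_val, x_min = 1e-8) {
  g <- function(x) mode_gradient(x, alpha, beta, F, V, phi0_val)
  opt <- stats::optimize(g, interval = c(x_min, 1), maximum = TRUE,
                         tol = 1e-12)
  if (opt$objective <= 0) return(NA_real_)   # g never positive: no mode
  x_up <- opt$maximum
  if (g(1) >= 0) return(NA_real_)            # density still rising at x = 1
  stats::uniroot(g, lower = x_up, upper = 1, tol = 1e-12)$root
}

#' Stationary Fokker-Planck density of a taxon's relative abundance
#'
#' Evaluates the steady-state solution `P0(x)` of the Fokker-Planck
#' equation associated with the community Langevin model on a log-spaced
#' grid over `(x_min, 1]`, normalizes it by numerical quadrature, and
#' locates its interior mode `x_M`. Two closed-form branches exist:
#'
#' * generic (`2*beta != 1 + alpha`):
#'   `P0(x) = C x^(-2 beta) exp[(2F/V^2) x^(1+alpha-2 beta)/(1+alpha-2 beta)
#'   - (phi0/V^2) x^(2-2 beta)/(1-beta)]`
#' * equal (`2*beta == 1 + alpha`):
#'   `P0(x) = C x^(2F/V^2 - 2 beta) exp[-(phi0/V^2) x^(2-2 beta)/(1-beta)]`
#'
#' The mode solves `F x^alpha - phi0 x - beta V^2 x^(2 beta - 1) = 0`
#' (zero of the log-density derivative) and is refined by root finding; the
#' presence of an interior mode on (0, 1) defines the ordered phase.
#'
#' @param alpha,beta Drift and noise exponents (`alpha < 1`, `beta != 1`).
#' @param F Fitness of the focal taxon (> 0).
#' @param V Noise amplitude (> 0).
#' @param phi0_val Stationary normalization drift; default `F`
#'   (dominant-taxon approximation). Use [phi0()] of the full fitness
#'   vector when available.
#' @param grid_size Number of log-spaced grid points (default 1024).
#' @param x_min Lower cutoff of the physical range (default 1e-8).
#'
#' @return Object of class `steady_state`: list with `grid`, `density`
#'   (normalized so the quadrature integral is 1), `log_density_unnorm`,
#'   `norm_constant`, `x_M` (NA when no interior mode), `branch`
#'   (`"generic"` or `"equal"`), and the parameters. `as_tibble()` returns
#'   the `(grid, density)` table.
#' @examples
#' ss <- steady_state_pdf(alpha = 0.75, beta = 0.75, F = 1, V = 0.2)
#' ss$x_M
#' @export
steady_state_pdf <- function(alpha, beta, F, V, phi0_val = F,
                             grid_size = 1024L, x_min = 1e-8) {
  if (V <= 0) stop("V must be > 0", call. = FALSE)
  if (alpha >= 1) stop("alpha must be < 1", call. = FALSE)
  if (abs(beta - 1) < 1e-12) stop("beta = 1 is not supported", call. = FALSE)
  if (F <= 0) stop("F must be > 0", call. = FALSE)
  eq_branch <- abs(2 * beta - (1 + alpha)) < 1e-12

  grid <- exp(seq(log(x_min), 0, length.out = grid_size))
  logp <- log_density_unnorm(grid, alpha, beta, F, V, phi0_val)
  if (any(!is.finite(logp))) {
    stop("non-finite log-density on the grid; check parameters", call. = FALSE)
  }
  m <- max(logp)
  p_rel <- exp(logp - m)
  # trapezoid in x over the log-spaced grid
  z_rel <- sum(diff(grid) * (p_rel[-1] + p_rel[-length(grid)]) / 2)
  if (!is.finite(z_rel) || z_rel <= 0) {
    stop("density not integrable on (x_min, 1]", call. = FALSE)
  }
  density <- p_rel / z_rel
  norm_constant <- exp(-m) / z_rel   # P0 = norm_constant * exp(logp)

  x_M <- find_interior_mode(alpha, beta, F, V, phi0_val, x_min = x_min)

  structure(
    list(grid = grid, density = density, log_density_unnorm = logp,
         norm_constant = norm_constant, x_M = x_M,
         branch = if (eq_branch) "equal" else "generic",
         alpha = alpha, beta = beta, F = F, V = V, phi0_val = phi0_val,
         x_min = x_min),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>", x$branch, "branch | alpha =", x$alpha,
      "beta =", x$beta, "F =", x$F, "V =", x$V, "\n")
  if (is.na(x$x_M)) {
    cat("  no interior mode on (0, 1): disordered (noise-induced) phase\n")
  } else {
    cat("  interior mode x_M =", signif(x$x_M, 6), "(ordered phase)\n")
  }
  invisible(x)
}

#' @method as_tibble steady_state
#' @export
as_tibble.steady_state <- function(x, ...) {
  tibble::tibble(x = x$grid, density = x$density)
}

#' @rdname steady_state_pdf
#' @param object A `steady_state`.
#' @param ... Unused.
#' @method autoplot steady_state
#' @export
autoplot.steady_state <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative abundance x", y = "stationary density P0(x)",
                  title = sprintf("%s branch, %s phase", object$branch,
                                  if (is.na(object$x_M)) "disordered"
                                  else "ordered"))
  if (!is.na(object$x_M)) {
    p <- p + ggplot2::geom_vline(xintercept = object$x_M,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Critical fitness at which the interior mode disappears
#'
#' For fixed noise amplitude `V`, the smallest fitness whose stationary
#' density still has an interior maximum on (0, 1). Closed forms:
#' `F_crit^2 = 4 beta phi0 V^2` when `beta = alpha != 1` (which becomes
#' `F_crit = 4 beta V^2`, i.e. `3 V^2` at `beta = 0.75`, when the focal
#' taxon dominates `phi0` so that `phi0 = F`), and `F_crit = beta V^2` when
#' `2 beta = 1 + alpha`. Outside these cases — or when
#' `method = "bisection"` is forced — the critical value is found by
#' bisection on the interior-mode predicate, which is monotone in `F`.
#'
#' @inheritParams steady_state_pdf
#' @param phi0_val Fixed `phi0`, or `NULL` (default) for the
#'   dominant-taxon self-consistent case `phi0 = F`.
#' @param method `"auto"` (closed form where available), `"closed_form"`,
#'   or `"bisection"`.
#' @param tol Relative bisection tolerance.
#' @param upper Upper end of the bisection bracket.
#' @return The critical fitness `F_crit`.
#' @export
critical_fitness <- function(alpha, beta, V, phi0_val = NULL,
                             method = c("auto", "closed_form", "bisection"),
                             tol = 1e-6, upper = NULL, x_min = 1e-8) {
  method <- match.arg(method)
  self_consistent <- is.null(phi0_val)
  closed <- NA_real_
  if (abs(beta - alpha) < 1e-12 && abs(beta - 1) > 1e-12) {
    closed <- if (self_consistent) 4 * beta * V^2
              else sqrt(4 * beta * phi0_val * V^2)
  } else if (abs(2 * beta - (1 + alpha)) < 1e-12) {
    closed <- beta * V^2
  }
  if (method == "closed_form" || (method == "auto" && !is.na(closed))) {
    if (is.na(closed)) {
      stop("no closed-form phase line for these exponents", call. = FALSE)
    }
    return(closed)
  }
  # bisection on the interior-mode predicate; the ordered region can be an
  # interval in F (the mode can exit through either end of (0, 1)), so first
  # locate any ordered F by log-spaced scan, then bisect its lower edge
  has_mode <- function(f) {
    p0 <- if (self_consistent) f else phi0_val
    !is.na(find_interior_mode(alpha, beta, f, V, p0, x_min = x_min))
  }
  lo <- 1e-8
  hi <- if (!is.null(upper)) upper else max(1, 10 * V^2, 10 * V)
  f_ord <- NA_real_
  for (attempt in 1:6) {
    cand <- 10^seq(log10(lo * 10), log10(hi), length.out = 120)
    hit <- which(vapply(cand, has_mode, logical(1)))
    if (length(hit) > 0L) {
      f_ord <- cand[hit[1L]]
      break
    }
    hi <- hi * 100
  }
  if (is.na(f_ord)) {
    stop("no ordered phase found up to F = ", hi, call. = FALSE)
  }
  if (has_mode(lo)) return(lo)
  hi <- f_ord
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (has_mode(mid)) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}

#' Classify the phase of a taxon's stationary dynamics
#'
#' A microbiota taxon is in the ordered (stable) phase when its stationary
#' Fokker-Planck density has a maximum at some interior composition
#' `0 < x < 1`; when noise pushes the maximum out of the physical interval
#' the phase is disordered (noise-induced instability).
#'
#' @inheritParams steady_state_pdf
#' @param phi0_val Normalization drift; `NULL` (default) uses the
#'   dominant-taxon self-consistent value `phi0 = F`.
#' @param ... Passed to [critical_fitness()].
#' @return A one-row tibble: `phase` (`"ordered"`/`"disordered"`), `x_M`,
#'   `F_crit`, `margin = F - F_crit`.
#' @examples
#' classify_phase(alpha = 0.75, beta = 0.75, F = 1, V = 0.2)
#' @export
classify_phase <- function(alpha, beta, F, V, phi0_val = NULL, ...) {
  p0 <- if (is.null(phi0_val)) F else phi0_val
  x_M <- find_interior_mode(alpha, beta, F, V, p0)
  f_crit <- critical_fitness(alpha, beta, V, phi0_val = phi0_val, ...)
  tibble::tibble(
    phase = if (!is.na(x_M)) "ordered" else "disordered",
    x_M = x_M,
    F_crit = f_crit,
    margin = F - f_crit
  )
}

stationary_loglik <- function(f, series, alpha, beta, V, phi0_val,
                              x_min = 1e-8, grid_size = 2048L) {
  p0 <- if (is.null(phi0_val)) f else phi0_val
  grid <- exp(seq(log(x_min), 0, length.out = grid_size))
  lp_grid <- log_density_unnorm(grid, alpha, beta, f, V, p0)
  m <- max(lp_grid)
  z <- sum(diff(grid) * (exp(lp_grid[-1] - m) +
                           exp(lp_grid[-length(grid)] - m)) / 2)
  lp <- log_density_unnorm(series, alpha, beta, f, V, p0)
  sum(lp) - length(series) * (m + log(z))
}

#' Infer taxon fitness from an observed abundance series
#'
#' Estimates the fitness `F` of a taxon from the fluctuations of its
#' relative-abundance series, assuming the series samples the stationary
#' regime of the Langevin model (the equilibrium reading of the
#' fluctuation-dissipation relation): `F` maximizes the stationary
#' log-likelihood `sum_t log P0(x_t; F, V, alpha, beta, phi0)` treating
#' observations as independent draws from the steady state.
#'
#' An alternative moment estimator (`method = "autocorrelation"`) reads
#' `F` as the inverse of the exponential autocorrelation time of the
#' series, the relaxation-rate interpretation of fitness.
#'
#' @param series Numeric vector of relative abundances in (0, 1], length
#'   >= 5.
#' @param V Noise amplitude (> 0), typically the fitted Taylor `V`.
#' @param alpha,beta Model exponents (defaults 0.75).
#' @param phi0_val Fixed normalization drift, or `NULL` (default) to tie
#'   `phi0 = F` self-consistently (dominant-taxon approximation).
#' @param method `"stationary"` (default) or `"autocorrelation"`.
#' @param interval Search bracket for `F`.
#' @param dt_obs Sampling interval of the series (autocorrelation method
#'   only).
#' @return One-row tibble: `F`, `logLik` (NA for the autocorrelation
#'   method), `boundary` (TRUE when the optimum hit the search bracket).
#' @export
infer_fitness <- function(series, V, alpha = 0.75, beta = 0.75,
                          phi0_val = NULL,
                          method = c("stationary", "autocorrelation"),
                          interval = c(1e-4, 1e4), dt_obs = 1) {
  method <- match.arg(method)
  if (length(series) < 5L) stop("series must have length >= 5", call. = FALSE)
  if (V <= 0) stop("V must be > 0", call. = FALSE)
  if (any(!is.finite(series)) || any(series <= 0) || any(series > 1)) {
    stop("series values must be finite and in (0, 1]", call. = FALSE)
  }

  if (method == "autocorrelation") {
    ac <- stats::acf(series, lag.max = 1, plot = FALSE)$acf[2]
    if (!is.finite(ac) || ac <= 0 || ac >= 1) {
      return(tibble::tibble(F = NA_real_, logLik = NA_real_, boundary = TRUE))
    }
    return(tibble::tibble(F = -log(ac) / dt_obs, logLik = NA_real_,
                          boundary = FALSE))
  }

  obj <- function(lf) {
    stationary_loglik(10^lf, series, alpha, beta, V, phi0_val)
  }
  opt <- stats::optimize(obj, interval = log10(interval), maximum = TRUE,
                         tol = 1e-6)
  lf <- opt$maximum
  span <- diff(log10(interval))
  boundary <- (lf - log10(interval[1]) < 0.01 * span) ||
    (log10(interval[2]) - lf < 0.01 * span)
  if (boundary) {
    warning("fitness optimum at the search bracket (bracket: ",
            interval[1], " .. ", interval[2], "); estimate unreliable")
  }
  tibble::tibble(F = 10^lf, logLik = opt$objective, boundary = boundary)
}

#' Infer per-taxon fitness with a self-consistent phi0
#'
#' Runs [infer_fitness()] for every taxon of a relative abundance table,
#' then iterates: the inferred fitness vector defines a new
#' `phi0 = (sum F_i^(1/(1-alpha)))^(1-alpha)`, each taxon is re-optimized
#' at that fixed `phi0`, until `phi0` stabilizes.
#'
#' @param table A relative [abundance_table()].
#' @param V,alpha,beta As in [infer_fitness()].
#' @param max_iter,tol Self-consistency loop controls.
#' @param min_mean Taxa with temporal mean below this are skipped.
#' @return A tibble: `taxon_id`, `F`, `logLik`, `boundary`, plus the final
#'   `phi0` as an attribute `"phi0"`.
#' @export
infer_fitness_community <- function(table, V, alpha = 0.75, beta = 0.75,
                                    max_iter = 10L, tol = 1e-3,
                                    min_mean = 1e-6) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$is_relative) stop("table must be relative", call. = FALSE)
  m <- table$counts
  keep <- rowMeans(m) >= min_mean
  m <- pmin(pmax(m[keep, , drop = FALSE], 1e-8), 1)

  est <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    infer_fitness(m[i, ], V = V, alpha = alpha, beta = beta)
  })
  p0 <- phi0(est$F, alpha)
  for (it in seq_len(max_iter)) {
    est <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
      infer_fitness(m[i, ], V = V, alpha = alpha, beta = beta, phi0_val = p0)
    })
    p0_new <- phi0(est$F, alpha)
    if (abs(p0_new - p0) / p0 < tol) {
      p0 <- p0_new
      break
    }
    p0 <- p0_new
  }
  out <- dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)), est)
  attr(out, "phi0") <- p0
  out
}
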