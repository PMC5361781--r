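#' Poisson community generator
#'
#' Independent Poisson counts per taxon and timepoint. A community whose
#' per-taxon fluctuations are Poisson (SD = sqrt(mean)) sits in the
#' beta = 1/2 universal class of Taylor's law, making this the null
#' generator for that class.
#'
#' @param means Expected counts per taxon (> 0); spanning several orders of
#'   magnitude mimics real abundance distributions. Default 50 taxa
#'   log-spaced over 10^1..10^5.
#' @param n_timepoints Number of timepoints (default 100).
#' @param seed Integer seed.
#' @return An [abundance_table()] of counts (times 0, 1, 2, ...).
#' @export
gen_poisson_community <- function(means = 10^seq(1, 5, length.out = 50),
                                  n_timepoints = 100L, seed = NULL) {
  if (any(means <= 0)) stop("means must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- length(means)
  m <- matrix(stats::rpois(k * n_timepoints, lambda = rep(means, n_timepoints)),
              nrow = k,
              dimnames = list(sprintf("taxon_%03d", seq_len(k)), NULL))
  abundance_table(m, times = seq_len(n_timepoints) - 1)
}

#' Exponential community generator
#'
#' Independent exponential abundances per taxon and timepoint (SD equal to
#' the mean), the beta = 1 universal class of Taylor's law.
#'
#' @inheritParams gen_poisson_community
#' @return An [abundance_table()] of (continuous, non-negative) abundances.
#' @export
gen_exponential_community <- function(means = 10^seq(1, 5, length.out = 50),
                                      n_timepoints = 100L, seed = NULL) {
  if (any(means <= 0)) stop("means must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- length(means)
  m <- matrix(stats::rexp(k * n_timepoints, rate = rep(1 / means, n_timepoints)),
              nrow = k,
              dimnames = list(sprintf("taxon_%03d", seq_len(k)), NULL))
  abundance_table(m, times = seq_len(n_timepoints) - 1)
}

#' Exact-Taylor community generator
#'
#' Draws each taxon's series from a positive-truncated Normal with mean
#' `mu_i` and SD exactly `V * mu_i^beta`, so the community obeys Taylor's
#' law by construction — the fixture for validating the fitting machinery.
#' Feasibility requires `V * mu^beta < mu / 2` for every taxon (the SD must
#' be well below the mean or truncation at zero distorts the target law),
#' which bounds how small the means may be for a given `(V, beta)`.
#'
#' @param V,beta Taylor parameters to build in.
#' @param means Per-taxon means; default 60 taxa log-spaced over
#'   \[0.02, 0.8\] (for typical `(V, beta)` the SD < mean/2 constraint
#'   rules out very rare taxa).
#' @param n_timepoints Number of timepoints (default 50).
#' @param seed Integer seed.
#' @param renormalize If `TRUE` each timepoint column is renormalized to
#'   sum to 1 and the table marked relative; off by default because the
#'   closure perturbs the built-in law.
#' @return An [abundance_table()] (relative iff `renormalize`).
#' @export
gen_exact_taylor <- function(V, beta,
                             means = 10^seq(log10(0.02), log10(0.8),
                                            length.out = 60),
                             n_timepoints = 50L, seed = NULL,
                             renormalize = FALSE) {
  if (V < 0) stop("V must be >= 0", call. = FALSE)
  sds <- V * means^beta
  if (any(sds >= means / 2)) {
    stop("infeasible: V * mean^beta >= mean/2 for ",
         sum(sds >= means / 2), " taxa; raise the means", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(means)
  m <- matrix(stats::rnorm(k * n_timepoints, mean = rep(means, n_timepoints),
                           sd = rep(sds, n_timepoints)),
              nrow = k,
              dimnames = list(sprintf("taxon_%03d", seq_len(k)), NULL))
  # positive truncation: redraw the (rare, < 2.3 sigma) non-positive values
  bad <- which(m <= 0)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    mu <- rep(means, n_timepoints)[bad]
    sg <- rep(sds, n_timepoints)[bad]
    m[bad] <- stats::rnorm(length(bad), mu, sg)
    bad <- which(m <= 0)
    guard <- guard + 1L
  }
  m[m <= 0] <- .Machine$double.eps
  tab <- abundance_table(m, times = seq_len(n_timepoints) - 1)
  if (renormalize) tab <- to_relative(tab)
  tab
}

#' Langevin cohort generator
#'
#' Simulates a multi-subject longitudinal cohort with the community
#' Langevin model. Each subject's series is integrated interval by
#' interval with the interval's own noise amplitude (e.g. a baseline `V`
#' during healthy periods and an elevated `V` during an antibiotic
#' course), continuing from the previous interval's final state; the
#' trajectory is sampled once per "day" and converted to sequencing-like
#' counts by a multinomial draw at the stated depth.
#'
#' @param n_subjects Number of subjects.
#' @param n_taxa Taxa per subject.
#' @param n_timepoints Sampled days per subject.
#' @param schedule A tibble/data frame with columns `subject`, `from`,
#'   `to` (day range, inclusive), `label`, `V` overriding the baseline
#'   noise per interval; `NULL` for an all-healthy cohort.
#' @param V Baseline noise amplitude.
#' @param alpha,beta Langevin exponents.
#' @param F_range Fitness values are drawn log-uniformly within this range
#'   per taxon (fixed per subject), producing the wide dominance spectrum
#'   of real communities.
#' @param depth Multinomial sequencing depth per sample (default 50000);
#'   `NULL` keeps exact relative abundances.
#' @param burn_in Days of burn-in discarded before sampling starts.
#' @param steps_per_day Euler-Maruyama steps per day.
#' @param seed Integer seed for the whole cohort.
#' @param study_id Study label attached to subject IDs.
#'
#' @return A named list of [abundance_table()]s (counts unless
#'   `depth = NULL`), one per subject, with per-day interval labels.
#' @examples
#' cohort <- gen_langevin_cohort(n_subjects = 2, n_taxa = 20,
#'                               n_timepoints = 10, seed = 1,
#'                               burn_in = 2, depth = 10000)
#' cohort[[1]]
#' @export
gen_langevin_cohort <- function(n_subjects = 3L, n_taxa = 50L,
                                n_timepoints = 30L, schedule = NULL,
                                V = 0.05, alpha = 0.75, beta = 0.75,
                                F_range = c(0.5, 5), depth = 50000L,
                                burn_in = 10L, steps_per_day = 200L,
                                seed = NULL, study_id = "synthetic") {
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max, n_subjects)

  out <- lapply(seq_len(n_subjects), function(s) {
    set.seed(subj_seeds[s])
    F <- 10^stats::runif(n_taxa, log10(F_range[1]), log10(F_range[2]))
    names(F) <- sprintf("taxon_%03d", seq_len(n_taxa))
    days <- seq_len(n_timepoints) - 1L
    labels <- rep("healthy", n_timepoints)
    v_day <- rep(V, n_timepoints)
    if (!is.null(schedule)) {
      sch <- schedule[schedule$subject == s, , drop = FALSE]
      for (i in seq_len(nrow(sch))) {
        in_int <- days >= sch$from[i] & days <= sch$to[i]
        labels[in_int] <- sch$label[i]
        if ("V" %in% names(sch) && is.finite(sch$V[i])) {
          v_day[in_int] <- sch$V[i]
        }
      }
    }
    dt <- 1 / steps_per_day
    # burn-in at the baseline noise level
    x <- rep(1 / n_taxa, n_taxa)
    if (burn_in > 0) {
      sim <- simulate_langevin(F, V, alpha = alpha, beta = beta, x0 = x,
                               dt = dt, n_steps = burn_in * steps_per_day,
                               record_every = burn_in * steps_per_day)
      x <- sim$x[, ncol(sim$x)]
    }
    comp <- matrix(NA_real_, nrow = n_taxa, ncol = n_timepoints,
                   dimnames = list(names(F), NULL))
    comp[, 1L] <- x
    for (k in 2L:n_timepoints) {
      n_steps <- (days[k] - days[k - 1L]) * steps_per_day
      sim <- simulate_langevin(F, v_day[k], alpha = alpha, beta = beta,
                               x0 = comp[, k - 1L], dt = dt,
                               n_steps = n_steps, record_every = n_steps)
      comp[, k] <- sim$x[, ncol(sim$x)]
    }
    if (is.null(depth)) {
      abundance_table(comp, times = days,
                      subject_id = sprintf("%s_S%02d", study_id, s),
                      interval_labels = labels, is_relative = TRUE)
    } else {
      counts <- apply(comp, 2, function(p) stats::rmultinom(1, depth, p))
      rownames(counts) <- names(F)
      abundance_table(counts, times = days,
                      subject_id = sprintf("%s_S%02d", study_id, s),
                      interval_labels = labels)
    }
  })
  names(out) <- vapply(out, function(x) x$subject_id, character(1))
  out
}
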