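#' Inverse-variance weighted mean
#'
#' Weighted mean with normalized inverse-variance weights
#' `omega_i = (1/sigma_i^2) / sum_j (1/sigma_j^2)`, used to pool the Taylor
#' parameters of the healthy subjects of a study into the reference value.
#'
#' @param values Numeric vector of estimates (e.g. per-subject `V`).
#' @param errors Positive numeric vector of their uncertainties.
#' @return The weighted mean `sum(omega_i * values_i)`.
#' @examples
#' weighted_mean(c(0.1, 0.2), c(0.01, 0.02))  # weights 0.8, 0.2 -> 0.12
#' @export
weighted_mean <- function(values, errors) {
  w <- ivw_weights(values, errors)
  sum(w * values)
}

#' Inverse-variance weighted standard deviation
#'
#' The unbiased weighted spread of a healthy group:
#' `sqrt( sum(omega_i * (v_i - vhat)^2) / (1 - W2) )` with
#' `W2 = sum(omega_i^2)` and `vhat` the [weighted_mean()]. A single subject
#' makes the denominator vanish (`W2 = 1`), so at least two values are
#' required.
#'
#' @inheritParams weighted_mean
#' @return The weighted standard deviation; 0 (with a warning) when all
#'   values are identical.
#' @examples
#' weighted_sd(c(0.1, 0.2), c(0.01, 0.02))  # sqrt(0.0016/0.32) ~ 0.0707
#' @export
weighted_sd <- function(values, errors) {
  w <- ivw_weights(values, errors)
  if (length(values) < 2L) {
    stop("weighted_sd needs at least 2 values (1 - W2 = 0 for a single one)",
         call. = FALSE)
  }
  W2 <- sum(w^2)
  if (1 - W2 <= .Machine$double.eps) {
    stop("degenerate weights: 1 - W2 = 0 (all weight on one value)",
         call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    warning("all values identical: weighted SD is 0")
    return(0)
  }
  vhat <- sum(w * values)
  ss <- sum(w * (values - vhat)^2)
  sqrt(ss / (1 - W2))
}

ivw_weights <- function(values, errors) {
  if (length(values) == 0L) stop("no values", call. = FALSE)
  if (length(values) != length(errors)) {
    stop("values and errors lengths differ", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(!is.finite(errors))) {
    stop("non-finite values or errors", call. = FALSE)
  }
  if (any(errors <= 0)) stop("all errors must be > 0", call. = FALSE)
  w <- 1 / errors^2
  w / sum(w)
}

#' Standardize a study's Taylor parameters against its healthy subjects
#'
#' Builds the healthy reference of one study — inverse-variance weighted
#' mean and weighted SD of `V` and of `beta` over the healthy subjects —
#' and maps every subject (healthy or not) to standardized coordinates
#' `z = (value - mean) / SD` per parameter, with error bars divided by the
#' same SD. By construction the healthy subjects' standardized values have
#' weighted mean 0 and weighted SD 1. Studies are standardized
#' independently: subjects of one study never affect another's reference.
#'
#' @param points A data frame with one row per subject: columns
#'   `subject_id`, `V`, `err_V`, `beta`, `err_beta`, `healthy` (logical),
#'   and optionally `study_id` (must be a single study).
#' @param radius_68,radius_98 Zone radii passed to [zone_membership()].
#'
#' @return An object of class `study_standardization`: a list with
#'   `reference` (one-row tibble: `study_id`, `V_hat`, `sigma_V`,
#'   `beta_hat`, `sigma_beta`, `h`) and `points` (tibble with `z_V`,
#'   `z_V_err`, `z_beta`, `z_beta_err`, `zone` appended). `tidy()` returns
#'   the points table.
#' @examples
#' pts <- tibble::tibble(
#'   subject_id = c("A", "B", "C", "P"),
#'   V = c(0.10, 0.12, 0.11, 0.30), err_V = c(0.01, 0.012, 0.011, 0.03),
#'   beta = c(0.70, 0.72, 0.69, 0.75),
#'   err_beta = c(0.02, 0.02, 0.02, 0.03),
#'   healthy = c(TRUE, TRUE, TRUE, FALSE))
#' standardize_study(pts)
#' @export
standardize_study <- function(points, radius_68 = 1.0, radius_98 = 2.8) {
  points <- tibble::as_tibble(points)
  needed <- c("subject_id", "V", "err_V", "beta", "err_beta", "healthy")
  if (!all(needed %in% names(points))) {
    stop("points must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"study_id" %in% names(points)) points$study_id <- "study"
  if (length(unique(points$study_id)) != 1L) {
    stop("mixed study_ids: standardize one study at a time ",
         "(see standardize_cohort())", call. = FALSE)
  }
  if (any(points$err_V <= 0) || any(points$err_beta <= 0)) {
    stop("all parameter errors must be > 0", call. = FALSE)
  }
  h <- points[points$healthy, ]
  if (nrow(h) < 2L) {
    stop("need at least 2 healthy subjects to build a reference, got ",
         nrow(h), call. = FALSE)
  }
  ref <- tibble::tibble(
    study_id = points$study_id[1L],
    V_hat = weighted_mean(h$V, h$err_V),
    sigma_V = weighted_sd(h$V, h$err_V),
    beta_hat = weighted_mean(h$beta, h$err_beta),
    sigma_beta = weighted_sd(h$beta, h$err_beta),
    h = nrow(h)
  )
  if (ref$sigma_V == 0 || ref$sigma_beta == 0) {
    stop("healthy group has zero spread in V or beta; cannot standardize",
         call. = FALSE)
  }
  pts <- dplyr::mutate(
    points,
    z_V = (.data$V - ref$V_hat) / ref$sigma_V,
    z_V_err = .data$err_V / ref$sigma_V,
    z_beta = (.data$beta - ref$beta_hat) / ref$sigma_beta,
    z_beta_err = .data$err_beta / ref$sigma_beta
  )
  pts$zone <- zone_membership(pts$z_V, pts$z_beta,
                              radius_68 = radius_68, radius_98 = radius_98)
  structure(list(reference = ref, points = pts),
            class = "study_standardization")
}

#' Standardize several studies at once
#'
#' Applies [standardize_study()] within each `study_id` group and binds the
#' standardized points; the per-study isolation of the references is
#' preserved.
#'
#' @inheritParams standardize_study
#' @return A list with `reference` (one row per study) and `points` (all
#'   subjects, standardized within their own study).
#' @export
standardize_cohort <- function(points, radius_68 = 1.0, radius_98 = 2.8) {
  points <- tibble::as_tibble(points)
  if (!"study_id" %in% names(points)) points$study_id <- "study"
  parts <- lapply(split(points, points$study_id), standardize_study,
                  radius_68 = radius_68, radius_98 = radius_98)
  list(reference = dplyr::bind_rows(lapply(parts, `[[`, "reference")),
       points = dplyr::bind_rows(lapply(parts, `[[`, "points")))
}

#' @export
print.study_standardization <- function(x, ...) {
  r <- x$reference
  cat("<study_standardization>", r$study_id, "| h =", r$h,
      "healthy subjects\n")
  cat(sprintf("  V_hat = %.4g (sigma %.3g) | beta_hat = %.4g (sigma %.3g)\n",
              r$V_hat, r$sigma_V, r$beta_hat, r$sigma_beta))
  print(x$points[, c("subject_id", "z_V", "z_beta", "zone")])
  invisible(x)
}

#' @rdname standardize_study
#' @param x A `study_standardization`.
#' @param ... Unused.
#' @method tidy study_standardization
#' @export
tidy.study_standardization <- function(x, ...) x$points

#' @rdname standardize_study
#' @method glance study_standardization
#' @export
glance.study_standardization <- function(x, ...) x$reference

#' Healthy-zone membership of standardized points
#'
#' Classifies standardized `(z_V, z_beta)` coordinates by Euclidean distance
#' from the healthy centroid: inside the 68%-confidence circle (radius 1 in
#' healthy-SD units), inside the 98% circle, or outside both.
#'
#' @param z_V,z_beta Standardized coordinates (vectorized).
#' @param radius_68,radius_98 Circle radii, `0 < radius_68 < radius_98`.
#'   Defaults 1.0 and 2.8.
#' @return A factor with levels `inside_68`, `inside_98`, `outside`.
#' @export
zone_membership <- function(z_V, z_beta, radius_68 = 1.0, radius_98 = 2.8) {
  if (radius_68 <= 0 || radius_98 <= radius_68) {
    stop("need 0 < radius_68 < radius_98", call. = FALSE)
  }
  r <- sqrt(z_V^2 + z_beta^2)
  factor(ifelse(r <= radius_68, "inside_68",
                ifelse(r <= radius_98, "inside_98", "outside")),
         levels = c("inside_68", "inside_98", "outside"))
}

#' Undo a study standardization
#'
#' Maps standardized coordinates back to raw `(V, beta)` using a stored
#' reference; the round trip through [standardize_study()] is exact.
#'
#' @param points Tibble with `z_V`, `z_beta` columns.
#' @param reference One-row reference tibble (from `$reference`).
#' @return `points` with `V` and `beta` recomputed.
#' @export
destandardize <- function(points, reference) {
  dplyr::mutate(tibble::as_tibble(points),
                V = .data$z_V * reference$sigma_V + reference$V_hat,
                beta = .data$z_beta * reference$sigma_beta + reference$beta_hat)
}

#' Plot the standardized parameter plane with the healthy zone
#'
#' Scatter of subjects in `(z_V, z_beta)` coordinates with the 68% and 98%
#' confidence circles of the healthy reference.
#'
#' @param object A `study_standardization` (or the list from
#'   [standardize_cohort()]).
#' @param radius_68,radius_98 Circle radii to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_standardization
#' @export
autoplot.study_standardization <- function(object, radius_68 = 1.0,
                                           radius_98 = 2.8, ...) {
  pts <- object$points
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- dplyr::bind_rows(
    tibble::tibble(z_V = radius_68 * cos(th), z_beta = radius_68 * sin(th),
                   which = "68% CL"),
    tibble::tibble(z_V = radius_98 * cos(th), z_beta = radius_98 * sin(th),
                   which = "98% CL")
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$z_V, y = .data$z_beta)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(group = .data$which,
                                    linetype = .data$which)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$z_beta - .data$z_beta_err,
                                        ymax = .data$z_beta + .data$z_beta_err),
                           width = 0, alpha = 0.4) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$z_V - .data$z_V_err,
                                         xmax = .data$z_V + .data$z_V_err),
                            height = 0, alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$healthy), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "standardized variability z(V)",
                  y = "standardized scaling index z(beta)",
                  linetype = NULL, colour = "healthy")
}
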