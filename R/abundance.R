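#' Longitudinal taxa abundance table for one subject
#'
#' Container for a taxa-by-timepoint abundance matrix from a single subject's
#' longitudinal series, together with sampling times (days since the first
#' sample) and per-timepoint interval labels (e.g. `"healthy"`,
#' `"antibiotic"`). All downstream analyses — per-taxon temporal statistics,
#' Taylor's-law fits, rank stability — start from this object.
#'
#' @param counts Numeric matrix, taxa in rows and timepoints in columns, with
#'   taxon IDs as row names. Non-negative. May hold raw counts or relative
#'   abundances (see `is_relative`).
#' @param times Numeric vector of sampling times (days), one per column,
#'   strictly increasing.
#' @param subject_id Subject identifier.
#' @param interval_labels Optional character vector of per-timepoint condition
#'   labels; defaults to `"healthy"` for every timepoint.
#' @param is_relative Logical; `TRUE` if columns are already proportions
#'   summing to 1.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `subject_id`, `taxon_ids`, `times`, `counts`, `interval_labels`,
#'   `is_relative`.
#'
#' @details A series needs at least 3 timepoints to support any temporal
#'   dispersion estimate; shorter series are rejected with an
#'   "insufficient series" error, mirroring the sample-selection rule used
#'   when assembling longitudinal cohorts.
#'
#' @examples
#' m <- matrix(c(2, 3, 5, 4, 4, 2, 1, 1, 1, 2, 3, 4), nrow = 3,
#'             dimnames = list(c("g_A", "g_B", "g_C"), NULL))
#' tab <- abundance_table(m, times = c(0, 3, 7, 10), subject_id = "S1")
#' tab
#' @export
abundance_table <- function(counts, times, subject_id = "subject",
                            interval_labels = NULL, is_relative = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (taxa x timepoints)", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("taxon_%03d", seq_len(nrow(counts)))
  }
  times <- as.numeric(times)
  if (length(times) != ncol(counts)) {
    stop("length(times) must equal ncol(counts)", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("insufficient series: need three or more timepoints, got ",
         length(times), call. = FALSE)
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain missing or non-finite values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("validation error: negative abundances found", call. = FALSE)
  }
  if (anyDuplicated(times)) {
    stop("duplicate sampling times are not allowed", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    ord <- order(times)
    times <- times[ord]
    counts <- counts[, ord, drop = FALSE]
    if (!is.null(interval_labels)) interval_labels <- interval_labels[ord]
  }
  if (is.null(interval_labels)) {
    interval_labels <- rep("healthy", length(times))
  }
  if (length(interval_labels) != length(times)) {
    stop("length(interval_labels) must equal length(times)", call. = FALSE)
  }
  if (isTRUE(is_relative)) {
    sums <- colSums(counts)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("is_relative = TRUE but some columns do not sum to 1", call. = FALSE)
    }
  }
  colnames(counts) <- NULL   # times are the canonical column identity
  structure(
    list(subject_id = as.character(subject_id),
         taxon_ids = rownames(counts),
         times = times,
         counts = counts,
         interval_labels = as.character(interval_labels),
         is_relative = isTRUE(is_relative)),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> subject", x$subject_id, "\n")
  cat("  ", nrow(x$counts), "taxa x", length(x$times), "timepoints,",
      if (x$is_relative) "relative abundances" else "counts", "\n")
  cat("  days", x$times[1], "to", x$times[length(x$times)],
      "| intervals:", paste(unique(x$interval_labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Tidy long form of an abundance table
#'
#' @param x An [abundance_table()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `taxon_id`, `time`, `label`,
#'   `abundance`.
#' @importFrom tibble as_tibble
#' @method as_tibble abundance_table
#' @export
as_tibble.abundance_table <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    taxon_id = rep(x$taxon_ids, times = length(x$times)),
    time = rep(x$times, each = length(x$taxon_ids)),
    label = rep(x$interval_labels, each = length(x$taxon_ids)),
    abundance = as.vector(x$counts)
  )
}

#' Read a longitudinal taxa table with its sample metadata
#'
#' Reads a taxa-by-sample table (TSV: first column taxon ID, optionally a
#' semicolon-delimited lineage string; remaining columns samples) plus a
#' sidecar metadata table with columns `sample_id`, `subject_id`, `day`,
#' `label`, and assembles one validated [abundance_table()] per subject.
#'
#' @param path Path to the taxa table (TSV, or BIOM when `format = "biom"`).
#' @param metadata Path to a metadata TSV, or a data frame with columns
#'   `sample_id`, `subject_id`, `day`, `label`.
#' @param format `"tsv"` (default) or `"biom"` (requires the biomformat
#'   package).
#' @param subject Optional subject ID to extract. Required when the metadata
#'   lists several subjects and `simplify` is `TRUE`.
#' @param simplify If `TRUE` (default) return a single `abundance_table`;
#'   otherwise a named list with one table per subject.
#'
#' @return An [abundance_table()] or a named list of them.
#' @export
read_taxa_table <- function(path, metadata, format = c("tsv", "biom"),
                            subject = NULL, simplify = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "tsv") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    mat <- as.matrix(raw[, -1, drop = FALSE])
    rownames(mat) <- as.character(raw[[1]])
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM input requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    mat <- as.matrix(biomformat::biom_data(b))
  }
  storage.mode(mat) <- "double"

  meta <- if (is.character(metadata)) {
    readr::read_tsv(metadata, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(metadata)
  }
  needed <- c("sample_id", "subject_id", "day", "label")
  if (!all(needed %in% names(meta))) {
    stop("metadata must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  missing_meta <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("no time stamp for sample(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(meta$day)) {
    bad <- meta$sample_id[is.na(meta$day)]
    stop("missing time stamp for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  subjects <- unique(meta$subject_id)
  if (!is.null(subject)) subjects <- intersect(subjects, subject)
  if (length(subjects) == 0) stop("no matching subjects in metadata", call. = FALSE)

  out <- lapply(subjects, function(s) {
    sm <- meta[meta$subject_id == s & meta$sample_id %in% colnames(mat), ]
    sm <- sm[order(sm$day), ]
    if (nrow(sm) < 3L) {
      stop("insufficient series: subject ", s, " has ", nrow(sm),
           " timepoints (three or more required)", call. = FALSE)
    }
    abundance_table(mat[, sm$sample_id, drop = FALSE],
                    times = sm$day, subject_id = s,
                    interval_labels = sm$label)
  })
  names(out) <- subjects
  if (simplify) {
    if (length(out) > 1L) {
      stop("metadata contains ", length(out),
           " subjects; pass `subject` or simplify = FALSE", call. = FALSE)
    }
    return(out[[1L]])
  }
  out
}

#' Write an abundance table and its metadata as TSV
#'
#' Inverse of [read_taxa_table()]: writes the taxa-by-sample matrix and a
#' sidecar metadata TSV in the dialect the reader expects.
#'
#' @param table An [abundance_table()].
#' @param path Output path for the taxa TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return Invisibly, `table`.
#' @export
write_taxa_table <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "abundance_table"))
  sample_ids <- sprintf("%s_t%03d", table$subject_id, seq_along(table$times))
  df <- tibble::as_tibble(table$counts, .name_repair = ~sample_ids)
  df <- dplyr::bind_cols(tibble::tibble(taxon_id = table$taxon_ids), df)
  readr::write_tsv(df, path, progress = FALSE)
  meta <- tibble::tibble(sample_id = sample_ids,
                         subject_id = table$subject_id,
                         day = table$times,
                         label = table$interval_labels)
  readr::write_tsv(meta, metadata_path, progress = FALSE)
  invisible(table)
}

#' Convert counts to relative abundances
#'
#' Divides every timepoint column by its total so columns sum to 1, the scale
#' on which temporal variability is analysed throughout the package.
#'
#' @param table An [abundance_table()] of counts.
#' @return The table with `is_relative = TRUE`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$is_relative) {
    stop("table is already relative", call. = FALSE)
  }
  totals <- colSums(table$counts)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)
    stop("zero-total timepoint(s) at day(s): ",
         paste(table$times[bad], collapse = ", "), call. = FALSE)
  }
  table$counts <- sweep(table$counts, 2, totals, "/")
  table$is_relative <- TRUE
  table
}

#' Subset an abundance table to one labelled interval
#'
#' A microbiota "state" is one (subject, interval) series; this extracts the
#' timepoints matching an interval label (e.g. the healthy period before a
#' perturbation).
#'
#' @param table An [abundance_table()].
#' @param label Interval label(s) to keep.
#' @return An [abundance_table()] restricted to the matching timepoints.
#' @export
subset_interval <- function(table, label) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- table$interval_labels %in% label
  if (sum(keep) < 3L) {
    stop("insufficient series: interval '", paste(label, collapse = "/"),
         "' has ", sum(keep), " timepoints (three or more required)",
         call. = FALSE)
  }
  abundance_table(table$counts[, keep, drop = FALSE],
                  times = table$times[keep],
                  subject_id = table$subject_id,
                  interval_labels = table$interval_labels[keep],
                  is_relative = table$is_relative)
}

#' Per-taxon temporal mean and dispersion
#'
#' Computes, for every retained taxon, the temporal mean relative abundance,
#' the temporal standard deviation (the dispersion entering Taylor's law),
#' the standard error of the mean, and the number of timepoints used. These
#' (mean, sd, sem) triples are the inputs to [fit_taylor_xweighted()].
#'
#' @param table A relative [abundance_table()].
#' @param min_nonzero Minimum number of timepoints at which a taxon must be
#'   detected (nonzero) to be retained; default 2 so that a dispersion is
#'   estimable.
#' @param timepoints Optional integer indices selecting a subset of
#'   timepoints.
#' @param drop_zeros If `FALSE` (default) zero abundances count as
#'   observations of 0; if `TRUE` the statistics use only the nonzero
#'   observations of each taxon.
#' @param check_relative If `TRUE` (default) require `is_relative`; set to
#'   `FALSE` for tables whose values are already proportions on an
#'   absolute scale that must not be re-closed (e.g. the exact-Taylor
#'   fixture generator, whose per-column renormalization would distort the
#'   built-in law).
#'
#' @return A tibble with columns `taxon_id`, `mean`, `sd`, `sem`, `n`.
#'   `sd` uses the n - 1 denominator; `sem = sd / sqrt(n)`.
#' @examples
#' m <- matrix(c(1, 2, 3, 9, 8, 7) * 0.1, nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g_A", "g_B"), NULL))
#' tab <- abundance_table(m, times = 0:2, is_relative = TRUE)
#' compute_stats(tab)
#' @export
compute_stats <- function(table, min_nonzero = 2L, timepoints = NULL,
                          drop_zeros = FALSE, check_relative = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (check_relative && !table$is_relative) {
    stop("compute_stats() expects a relative table; call to_relative() first",
         call. = FALSE)
  }
  if (min_nonzero < 1L) stop("min_nonzero must be >= 1", call. = FALSE)
  m <- table$counts
  if (!is.null(timepoints)) m <- m[, timepoints, drop = FALSE]
  if (ncol(m) < 3L) {
    stop("insufficient series: fewer than 3 selected timepoints", call. = FALSE)
  }

  nonzero <- rowSums(m > 0)
  keep <- nonzero >= min_nonzero
  if (!any(keep)) {
    stop("all taxa filtered out (min_nonzero = ", min_nonzero, ")",
         call. = FALSE)
  }
  m <- m[keep, , drop = FALSE]

  if (drop_zeros) {
    stats_one <- function(v) {
      v <- v[v > 0]
      c(mean(v), stats::sd(v), length(v))
    }
    s <- t(apply(m, 1, stats_one))
  } else {
    s <- cbind(rowMeans(m), apply(m, 1, stats::sd), ncol(m))
  }
  tibble::tibble(
    taxon_id = rownames(m),
    mean = unname(s[, 1]),
    sd = unname(s[, 2]),
    sem = unname(s[, 2] / sqrt(s[, 3])),
    n = as.integer(s[, 3])
  )
}
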