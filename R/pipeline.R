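#' Run the full stability analysis for one study
#'
#' Orchestrates the pipeline end to end: read (or accept) per-subject
#' abundance tables, split them into labelled interval states, fit Taylor's
#' law per state, standardize every state against the study's healthy
#' reference, diagnose each state's dynamical phase (ordered vs
#' noise-induced disordered), and compute rank-stability reports and
#' sliding-window parameter series per subject. All artifacts are written
#' under `out_dir` together with a JSON manifest (seeds, files, md5 hashes)
#' and a timing log; any stage failure aborts and removes partial outputs.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `study_id`; `input`, `metadata` (paths; optional when `tables` given);
#'   `healthy_label` (default `"healthy"`); `seed`; `fit` (list:
#'   `replicates`, `mode`); `window_size` (default 5); `rank` (list:
#'   `top_n`, `p`, `rsi_threshold`); `phase` (list: `alpha` — `NULL` to
#'   reuse the fitted Taylor beta for both exponents); `out_dir`.
#' @param tables Optional named list of [abundance_table()]s, bypassing
#'   file input (e.g. from [gen_langevin_cohort()]).
#'
#' @return Invisibly, the manifest list. Key outputs: `fits.json` (one
#'   record per state), `zspace.tsv` (standardized coordinates + zone),
#'   `phase.json`, `ranks_<subject>.tsv` / `rsi_<subject>.tsv` /
#'   `rv_dv_<subject>.tsv`, `windows_<subject>.tsv`, `manifest.json`,
#'   `run.log`.
#' @export
run_study <- function(config, tables = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(study_id = "study", healthy_label = "healthy", seed = 1L,
         fit = list(replicates = 1000L, mode = "loglog"),
         window_size = 5L,
         rank = list(top_n = 50L, p = 4, rsi_threshold = 0.70),
         phase = list(alpha = NULL),
         out_dir = "microstab_out"),
    config
  )
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_lines <- character(0)
  t_start <- Sys.time()
  log_stage <- function(stage, msg) {
    line <- sprintf("[%s] %-12s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
  }
  emit <- function(file) {
    written <<- c(written, file)
    file
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # ---- stage: input -------------------------------------------------------
  tables <- tryCatch({
    if (is.null(tables)) {
      tables <- read_taxa_table(cfg$input, cfg$metadata, simplify = FALSE)
    }
    tables <- lapply(tables, function(tb) {
      if (tb$is_relative) tb else to_relative(tb)
    })
    names(tables) <- vapply(tables, function(tb) tb$subject_id, character(1))
    tables
  }, error = function(e) fail("input", e))
  log_stage("input", paste(length(tables), "subject table(s)"))

  set.seed(cfg$seed)
  fit_seeds <- sample.int(.Machine$integer.max, 10000L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    fit_seeds[seed_i]
  }

  # ---- stage: taylor fits per (subject, interval) state -------------------
  states <- tryCatch({
    purrr::map_dfr(tables, function(tb) {
      purrr::map_dfr(unique(tb$interval_labels), function(lbl) {
        if (sum(tb$interval_labels == lbl) < 3L) return(NULL)
        st <- compute_stats(subset_interval(tb, lbl))
        fit <- fit_taylor_xweighted(st, n_replicates = cfg$fit$replicates,
                                    seed = next_seed(), mode = cfg$fit$mode)
        dplyr::mutate(glance(fit),
                      subject_id = tb$subject_id, interval = lbl,
                      state_id = paste(tb$subject_id, lbl, sep = ":"),
                      healthy = identical(lbl, cfg$healthy_label),
                      .before = 1)
      })
    })
  }, error = function(e) fail("taylor_fit", e))
  if (nrow(states) == 0) fail("taylor_fit", simpleError("no fittable states"))
  fits_path <- emit(file.path(cfg$out_dir, "fits.json"))
  jsonlite::write_json(states, fits_path, auto_unbox = TRUE, digits = NA)
  log_stage("taylor_fit", paste(nrow(states), "state fit(s)"))

  # ---- stage: standardization against the healthy reference ---------------
  zspace <- tryCatch({
    pts <- dplyr::transmute(states,
                            subject_id = .data$state_id,
                            study_id = cfg$study_id,
                            V = .data$V, err_V = .data$err_V,
                            beta = .data$beta, err_beta = .data$err_beta,
                            healthy = .data$healthy)
    standardize_study(pts)
  }, error = function(e) fail("standardization", e))
  z_path <- emit(file.path(cfg$out_dir, "zspace.tsv"))
  readr::write_tsv(zspace$points, z_path, progress = FALSE)
  log_stage("standardization",
            sprintf("h = %d healthy states", zspace$reference$h))

  # ---- stage: phase diagnosis per state ------------------------------------
  phase_tbl <- tryCatch({
    purrr::map_dfr(seq_len(nrow(states)), function(i) {
      row <- states[i, ]
      ab <- if (is.null(cfg$phase$alpha)) min(row$beta, 0.95) else
        cfg$phase$alpha
      tb <- subset_interval(tables[[row$subject_id]], row$interval)
      dom <- which.max(rowSums(tb$counts))
      series <- pmin(pmax(tb$counts[dom, ], 1e-8), 1)
      f_est <- infer_fitness(series, V = row$V, alpha = ab, beta = ab)
      diag <- classify_phase(alpha = ab, beta = ab, F = f_est$F, V = row$V)
      dplyr::mutate(diag, state_id = row$state_id, F = f_est$F, V = row$V,
                    alpha = ab, beta = ab, .before = 1)
    })
  }, error = function(e) fail("phase", e))
  phase_path <- emit(file.path(cfg$out_dir, "phase.json"))
  jsonlite::write_json(phase_tbl, phase_path, auto_unbox = TRUE, digits = NA)
  log_stage("phase", paste(sum(phase_tbl$phase == "ordered"), "of",
                           nrow(phase_tbl), "states ordered"))

  # ---- stage: rank stability per subject -----------------------------------
  tryCatch({
    for (tb in tables) {
      rm_ <- rank_over_time(tb, top_n = cfg$rank$top_n)
      rep_ <- rank_report(rm_, p = cfg$rank$p)
      readr::write_tsv(tibble::as_tibble(rm_),
                       emit(file.path(cfg$out_dir,
                                      paste0("ranks_", tb$subject_id, ".tsv"))),
                       progress = FALSE)
      readr::write_tsv(rep_$rsi,
                       emit(file.path(cfg$out_dir,
                                      paste0("rsi_", tb$subject_id, ".tsv"))),
                       progress = FALSE)
      readr::write_tsv(rep_$variability,
                       emit(file.path(cfg$out_dir,
                                      paste0("rv_dv_", tb$subject_id, ".tsv"))),
                       progress = FALSE)
    }
  }, error = function(e) fail("rank_stability", e))
  log_stage("rank_stability", paste(length(tables), "subject report(s)"))

  # ---- stage: sliding windows per subject ----------------------------------
  tryCatch({
    for (tb in tables) {
      if (length(tb$times) < cfg$window_size) next
      ws <- sliding_taylor(tb, window_size = cfg$window_size,
                           seed = next_seed())
      readr::write_tsv(ws,
                       emit(file.path(cfg$out_dir,
                                      paste0("windows_", tb$subject_id,
                                             ".tsv"))),
                       progress = FALSE)
    }
  }, error = function(e) fail("sliding_window", e))
  log_stage("sliding_window", "done")

  # ---- manifest + log -------------------------------------------------------
  manifest <- list(
    study_id = cfg$study_id,
    seed = cfg$seed,
    healthy_label = cfg$healthy_label,
    created = format(t_start, "%Y-%m-%d %H:%M:%S"),
    package_version = as.character(utils::packageVersion("microstab")),
    files = lapply(stats::setNames(written, basename(written)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  log_stage("manifest", paste(length(written), "artifact(s)"))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(manifest)
}
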