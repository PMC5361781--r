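# fixtures are built in code: small tables and on-disk TSV pairs

make_table <- function(m, times = seq_len(ncol(m)) - 1, relative = FALSE,
                       labels = NULL) {
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("g_%02d", seq_len(nrow(m)))
  }
  abundance_table(m, times = times, interval_labels = labels,
                  is_relative = relative)
}

# writes a taxa TSV + metadata TSV into a temp dir; returns the two paths
write_fixture_tsv <- function(counts, days, subject = "S1",
                              labels = rep("healthy", length(days)),
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sample_ids <- sprintf("%s_%02d", subject, seq_along(days))
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
  colnames(df) <- c("taxon_id", sample_ids)
  taxa_path <- file.path(dir, "taxa.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  readr::write_tsv(df, taxa_path, progress = FALSE)
  readr::write_tsv(
    data.frame(sample_id = sample_ids, subject_id = subject, day = days,
               label = labels),
    meta_path, progress = FALSE)
  list(taxa = taxa_path, meta = meta_path)
}

# relative table with known per-taxon values, columns need not sum to 1
make_relative_matrix <- function(...) {
  m <- rbind(...)
  rownames(m) <- sprintf("g_%02d", seq_len(nrow(m)))
  m
}
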