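# Shared fixtures, all built in code.

toy_records <- function(seqs, labels = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  if (is.null(labels)) labels <- rep("unknown", n)
  data.frame(id = ids, sequence = toupper(seqs), label = labels,
             species = NA_character_, gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

write_fasta_tmp <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

random_aa <- function(n, seed = 1) {
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(ab, sample(60:120, 1), replace = TRUE), collapse = ""),
    character(1)))
}

# Small cached synthetic pipeline shared by model-level tests.
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_pos = 60, n_neg = 60, seed = 42,
                              samples_per_dataset = 12)
      rec <- generate_sequences(cfg)
      prof <- generate_profiles(rec, noise_sd = 1, seed = 5)
      expr <- generate_expression(rec, cfg)
      meta <- meta_pcc_from_datasets(expr$datasets)
      rec <- expr$records
      knn <- knn_score_table(rec, meta,
                             knn_config(rec$gene_id, rec$label))
      x <- build_feature_matrix(rec, prof, knn)
      cache <<- list(config = cfg, records = rec, profiles = prof,
                     meta = meta, knn = knn, x = x)
    }
    cache
  }
})
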