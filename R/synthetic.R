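#' Synthetic-data generator configuration
#'
#' The generator emulates the statistical structure the predictor
#' assumes: a fraction of positive proteins carry an N-terminal
#' targeting signal whose first `signal_window` residues are enriched
#' in positively charged and hydrophobic residues (R, W, H, L, K, A,
#' Y, I) and depleted in acidic and other residues (D, E, V, N, G, P,
#' M); the remaining positives carry no N-terminal signal and are
#' recoverable only through global/co-expression information; and in
#' every expression dataset the positives load on a shared latent
#' factor (block co-expression) while negatives are independent noise.
#'
#' @param n_pos,n_neg class sizes.
#' @param seed integer master seed.
#' @param presequence_fraction fraction of positives carrying the
#'   N-terminal signal (default 0.7, the approximate share of
#'   annotated mitochondrial proteins with a 5-50 residue transit
#'   peptide).
#' @param signal_window length of the enriched N-terminal stretch.
#' @param enrich_up,enrich_down residues up-/down-weighted inside the
#'   signal window.
#' @param enrich_factor,deplete_factor multiplicative reweights for
#'   the two groups (defaults 2 and 0.5).
#' @param background background residue distribution (named 20-vector;
#'   default uniform).
#' @param coexpr_strength latent-factor loading of positives in the
#'   expression datasets (default 1, i.e. signal variance equals noise
#'   variance).
#' @param n_datasets,samples_per_dataset expression design.
#' @param length_range sequence length range (min >= 50).
#' @param unmapped_fraction fraction of proteins withheld from the
#'   protein-to-gene mapping table (exercises the five-zero
#'   co-expression fallback).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_pos = 400L, n_neg = 400L, seed = 1L,
                             presequence_fraction = 0.7,
                             signal_window = 22L,
                             enrich_up = c("R", "W", "H", "L", "K", "A",
                                           "Y", "I"),
                             enrich_down = c("D", "E", "V", "N", "G", "P",
                                             "M"),
                             enrich_factor = 2, deplete_factor = 0.5,
                             background = NULL,
                             coexpr_strength = 1,
                             n_datasets = 3L, samples_per_dataset = 20L,
                             length_range = c(80L, 300L),
                             unmapped_fraction = 0.1) {
  if (presequence_fraction < 0 || presequence_fraction > 1)
    stop("presequence_fraction must be in [0, 1]")
  if (length_range[1] < 50) stop("minimum sequence length must be >= 50")
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(all(names(background) == AA_ALPHABET))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seed = as.integer(seed),
                 presequence_fraction = presequence_fraction,
                 signal_window = as.integer(signal_window),
                 enrich_up = enrich_up, enrich_down = enrich_down,
                 enrich_factor = enrich_factor,
                 deplete_factor = deplete_factor,
                 background = background / sum(background),
                 coexpr_strength = coexpr_strength,
                 n_datasets = as.integer(n_datasets),
                 samples_per_dataset = as.integer(samples_per_dataset),
                 length_range = as.integer(length_range),
                 unmapped_fraction = unmapped_fraction),
            class = "generator_config")
}

signal_distribution <- function(config) {
  w <- config$background
  w[config$enrich_up] <- w[config$enrich_up] * config$enrich_factor
  w[config$enrich_down] <- w[config$enrich_down] * config$deplete_factor
  w / sum(w)
}

#' Generate labeled synthetic protein sequences
#'
#' Negatives and signal-free positives sample every position from the
#' background composition; signal-bearing positives sample their first
#' `signal_window` residues from the background reweighted by the
#' enrichment multipliers. Deterministic for a fixed config seed.
#'
#' @param config a [generator_config()].
#' @return record table with an extra logical column
#'   `has_presequence`.
#' @export
generate_sequences <- function(config = generator_config()) {
  sig <- signal_distribution(config)
  bg <- config$background
  with_seed(config$seed, {
    n <- config$n_pos + config$n_neg
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    has_sig <- c(runif(config$n_pos) < config$presequence_fraction,
                 rep(FALSE, config$n_neg))
    seqs <- character(n)
    for (i in seq_len(n)) {
      L <- lens[i]
      if (has_sig[i]) {
        w <- min(config$signal_window, L)
        head_res <- sample(AA_ALPHABET, w, replace = TRUE, prob = sig)
        tail_res <- sample(AA_ALPHABET, L - w, replace = TRUE, prob = bg)
        seqs[i] <- paste(c(head_res, tail_res), collapse = "")
      } else {
        seqs[i] <- paste(sample(AA_ALPHABET, L, replace = TRUE, prob = bg),
                         collapse = "")
      }
    }
    data.frame(id = c(sprintf("POS%04d", seq_len(config$n_pos)),
                      sprintf("NEG%04d", seq_len(config$n_neg))),
               sequence = seqs,
               label = rep(c("positive", "negative"),
                           c(config$n_pos, config$n_neg)),
               species = "synthetic",
               gene_id = NA_character_,
               has_presequence = has_sig,
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic per-protein profiles
#'
#' Substitution-fallback profile per record plus seeded Gaussian
#' perturbation, rounded back to integers so the parse/scale paths are
#' exercised exactly as with real ASCII profiles.
#'
#' @param records record table.
#' @param noise_sd standard deviation of the perturbation (0 gives the
#'   fallback exactly).
#' @param seed integer seed.
#' @return named list of unscaled `profile_matrix` objects.
#' @export
generate_profiles <- function(records, noise_sd = 1, seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(records)), function(i) {
      p <- substitution_fallback_profile(records$sequence[i],
                                         records$id[i])
      m <- p$mat
      if (noise_sd > 0)
        m <- round(m + rnorm(length(m), sd = noise_sd))
      profile_matrix(records$id[i], m, scaled = FALSE,
                     source = "substitution_fallback")
    })
    names(out) <- records$id
    out
  })
}

#' Generate block-structured synthetic expression datasets
#'
#' Each dataset contains one gene per record; in every sample the
#' positive genes share a latent factor with loading
#' `coexpr_strength` plus unit Gaussian noise, while negative genes
#' are pure noise, so positives co-express with each other but not
#' with negatives. Values are on the log2 scale by construction. A
#' configured fraction of proteins is withheld from the mapping table
#' to exercise the five-zero fallback path.
#'
#' @param records record table.
#' @param config a [generator_config()].
#' @return list with `datasets` (list of `expression_dataset`),
#'   `mapping` (data.frame protein_id/gene_id) and `records` (the
#'   input with `gene_id` attached for mapped proteins).
#' @export
generate_expression <- function(records, config = generator_config()) {
  n <- nrow(records)
  genes <- paste0("g_", records$id)
  pos <- records$label == "positive"
  with_seed(config$seed + 7L, {
    datasets <- lapply(seq_len(config$n_datasets), function(d) {
      s <- config$samples_per_dataset
      f <- rnorm(s)  # latent factor per sample
      m <- matrix(rnorm(n * s), n, s,
                  dimnames = list(genes, sprintf("S%02d", seq_len(s))))
      m[pos, ] <- m[pos, ] +
        config$coexpr_strength * matrix(f, sum(pos), s, byrow = TRUE)
      expression_dataset(sprintf("synth%02d", d), m, logged = TRUE)
    })
    n_unmapped <- round_half_up(config$unmapped_fraction * n)
    unmapped <- if (n_unmapped > 0) sample.int(n, n_unmapped) else integer(0)
    keep <- setdiff(seq_len(n), unmapped)
    mapping <- data.frame(protein_id = records$id[keep],
                          gene_id = genes[keep],
                          stringsAsFactors = FALSE)
    list(datasets = datasets, mapping = mapping,
         records = map_to_reference(records, mapping))
  })
}

#' Write a complete synthetic fixture tree
#'
#' Emits exactly the package's own input formats: a FASTA file, a
#' label table, one ASCII PSSM file per protein, tab-delimited
#' expression matrices with a manifest, and the protein-to-gene
#' mapping table.
#'
#' @param dir output directory (created if needed).
#' @param config a [generator_config()].
#' @param noise_sd profile perturbation passed to
#'   [generate_profiles()].
#' @return (invisibly) the list of generated objects.
#' @export
write_synthetic <- function(dir, config = generator_config(),
                            noise_sd = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- generate_sequences(config)
  profiles <- generate_profiles(records, noise_sd = noise_sd,
                                seed = config$seed + 3L)
  expr <- generate_expression(records, config)
  writeLines(paste0(">", records$id, "\n", records$sequence),
             file.path(dir, "sequences.fasta"))
  write.table(records[, c("id", "label")], file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  pdir <- file.path(dir, "pssm")
  dir.create(pdir, showWarnings = FALSE)
  for (id in names(profiles))
    write_pssm(profiles[[id]], records$sequence[records$id == id],
               file.path(pdir, paste0(id, ".pssm")))
  man <- data.frame(dataset_id = character(0), path = character(0),
                    n_samples = integer(0), logged = logical(0))
  for (ds in expr$datasets) {
    fn <- paste0(ds$dataset_id, ".tsv")
    tab <- data.frame(gene = rownames(ds$matrix), ds$matrix,
                      check.names = FALSE)
    write.table(tab, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    man <- rbind(man, data.frame(dataset_id = ds$dataset_id, path = fn,
                                 n_samples = ds$n_samples,
                                 logged = TRUE))
  }
  write.table(man, file.path(dir, "expression_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(expr$mapping, file.path(dir, "mapping.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(records = expr$records, profiles = profiles,
                 datasets = expr$datasets, mapping = expr$mapping))
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' Companion to [parse_pssm()]; used by the synthetic generator so
#' fixtures exercise the real parse path.
#'
#' @param profile an unscaled `profile_matrix` of integers.
#' @param sequence the protein sequence (residue column of the file).
#' @param path output path.
#' @export
write_pssm <- function(profile, sequence, path) {
  res <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(nrow(profile$mat) == length(res))
  # conventional PSI-BLAST column order
  ord <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- profile$mat[, ord, drop = FALSE]
  lines <- c("Last position-specific scoring matrix computed",
             paste0("            ", paste(sprintf("%3s", ord),
                                          collapse = " ")))
  for (i in seq_len(nrow(m)))
    lines <- c(lines,
               paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(m[i, ])),
                            collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
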