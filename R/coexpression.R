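#' Construct an expression dataset
#'
#' A genes x samples numeric matrix with unique gene identifiers as
#' rownames. `logged = TRUE` marks values already on the log2 scale.
#'
#' @param dataset_id dataset identifier.
#' @param matrix genes x samples numeric matrix with gene rownames.
#' @param logged are values already log2-transformed?
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, logged = FALSE) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stop("matrix needs gene rownames")
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene ids")
  if (ncol(matrix) < 2L) stop("need at least 2 samples")
  structure(list(dataset_id = dataset_id, matrix = matrix,
                 n_samples = ncol(matrix), logged = logged),
            class = "expression_dataset")
}

#' Log2-transform an expression dataset
#'
#' Applies `x -> log2(x + pseudocount)` elementwise. A dataset flagged
#' as already logged is returned unchanged; negative values in an
#' unlogged dataset are an error.
#'
#' @param dataset an `expression_dataset`.
#' @param pseudocount added before taking logs.
#' @return the transformed `expression_dataset` (flagged logged).
#' @export
log2_transform <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$logged) return(dataset)
  if (min(dataset$matrix) < 0)
    stop("negative expression values in unlogged dataset '",
         dataset$dataset_id, "'")
  expression_dataset(dataset$dataset_id,
                     log2(dataset$matrix + pseudocount), logged = TRUE)
}

#' Per-dataset Pearson correlation matrix
#'
#' Standard Pearson correlation between gene expression profiles over
#' samples. Zero-variance genes cannot be correlated; their rows and
#' columns are `NA` and their ids are recorded in the `excluded`
#' attribute.
#'
#' @param dataset an `expression_dataset` (log scale recommended).
#' @return symmetric genes x genes correlation matrix.
#' @export
pearson_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- dataset$matrix
  sds <- apply(m, 1, sd)
  r <- suppressWarnings(cor(t(m)))
  zero <- rownames(m)[sds == 0]
  r[rownames(m) %in% zero, ] <- NA
  r[, rownames(m) %in% zero] <- NA
  attr(r, "excluded") <- zero
  r
}

#' Combine per-dataset correlations into meta-Pearson coefficients
#'
#' Fisher meta-analysis of gene-pair correlations across datasets:
#' each r is clamped to |r| <= 1 - 1e-6, z-transformed
#' (`atanh`), averaged with inverse-variance weights `n - 3`, and
#' back-transformed with `tanh`. Pairs covered by no dataset are
#' missing (`NA`) and rank below all covered pairs in
#' [knn_scores()]; per-pair coverage counts are recorded.
#'
#' @param correlations list of per-dataset correlation matrices (gene
#'   rownames; `NA` for excluded pairs), e.g. from [pearson_matrix()].
#' @param n_samples integer vector of per-dataset sample counts.
#' @return object of class `meta_pcc`: list with `genes`, `r`
#'   (symmetric meta-correlation matrix, diagonal 1 for covered genes)
#'   and `coverage` (contributing-dataset counts).
#' @export
meta_combine <- function(correlations, n_samples) {
  stopifnot(length(correlations) == length(n_samples))
  if (all(n_samples <= 3))
    stop("all datasets have n <= 3 samples; Fisher weights (n - 3) vanish")
  genes <- sort(unique(unlist(lapply(correlations, rownames))))
  G <- length(genes)
  WZ <- matrix(0, G, G, dimnames = list(genes, genes))
  W <- matrix(0, G, G, dimnames = list(genes, genes))
  cov <- matrix(0L, G, G, dimnames = list(genes, genes))
  clamp <- 1 - 1e-6
  for (d in seq_along(correlations)) {
    w <- n_samples[d] - 3
    if (w <= 0) next
    r <- correlations[[d]]
    g <- rownames(r)
    ix <- match(g, genes)
    z <- atanh(pmin(pmax(r, -clamp), clamp))
    ok <- is.finite(z)
    zz <- ifelse(ok, z, 0)
    WZ[ix, ix] <- WZ[ix, ix] + w * zz
    W[ix, ix] <- W[ix, ix] + w * ok
    cov[ix, ix] <- cov[ix, ix] + ok
  }
  meta <- tanh(WZ / W)           # 0/0 -> NaN for uncovered pairs
  meta[W == 0] <- NA
  diag(meta)[diag(cov) > 0] <- 1
  structure(list(genes = genes, r = meta, coverage = cov),
            class = "meta_pcc")
}

#' @export
print.meta_pcc <- function(x, ...) {
  cat("Meta-PCC matrix:", length(x$genes), "genes; coverage",
      min(x$coverage), "-", max(x$coverage), "datasets per pair\n")
  invisible(x)
}

#' KNN scoring configuration
#'
#' @param train_genes gene ids of the training proteins.
#' @param train_labels matching labels (`positive`/`negative` or
#'   logical).
#' @param k_percent neighbourhood sizes as percentages of the training
#'   size (defaults 0.25, 0.5, 1, 2, 4).
#' @return object of class `knn_config`.
#' @export
knn_config <- function(train_genes, train_labels,
                       k_percent = c(0.25, 0.5, 1, 2, 4)) {
  if (length(train_genes) == 0L) stop("empty training set")
  if (length(train_genes) != length(train_labels))
    stop("train_genes and train_labels lengths differ")
  if (any(k_percent <= 0 | k_percent >= 100))
    stop("k_percent values must be in (0, 100)")
  keep <- !is.na(train_genes)
  structure(list(train_genes = train_genes[keep],
                 train_labels = as_binary_label(train_labels[keep]) ==
                   "positive",
                 k_percent = k_percent),
            class = "knn_config")
}

#' Co-expression KNN scores for one gene
#'
#' For each neighbourhood size K (% of training size, neighbour count
#' `k = max(1, round(K/100 * N_train))`, round-half-up), training genes
#' are ranked by meta-PCC with the query (descending; the query's own
#' gene excluded; ties, and pairs with no dataset coverage, broken /
#' ranked last deterministically by gene id) and the fraction of
#' positives among the top k is returned.
#'
#' @param query_gene gene id present in `meta` (callers substitute five
#'   zeros for unmapped proteins; see [build_feature_matrix()]).
#' @param meta a `meta_pcc` object.
#' @param config a [knn_config()].
#' @return named numeric vector, one score in \[0, 1\] per K.
#' @export
knn_scores <- function(query_gene, meta, config) {
  stopifnot(inherits(meta, "meta_pcc"), inherits(config, "knn_config"))
  if (!query_gene %in% meta$genes)
    stop("query gene '", query_gene, "' not in meta-PCC matrix")
  n_train <- length(config$train_genes)
  cand <- config$train_genes != query_gene
  genes <- config$train_genes[cand]
  labels <- config$train_labels[cand]
  r <- rep(NA_real_, length(genes))
  known <- genes %in% meta$genes
  r[known] <- meta$r[query_gene, genes[known]]
  key <- ifelse(is.na(r), -Inf, r)
  ord <- order(-key, genes)
  out <- numeric(length(config$k_percent))
  for (i in seq_along(config$k_percent)) {
    k <- max(1L, round_half_up(config$k_percent[i] / 100 * n_train))
    k <- min(k, length(genes))
    out[i] <- mean(labels[ord[seq_len(k)]])
  }
  setNames(out, sprintf("K%g", config$k_percent))
}

#' KNN score table for a set of records
#'
#' Convenience wrapper: one row of [knn_scores()] per record; records
#' without a `gene_id` or whose gene is absent from the meta-PCC
#' matrix get five zeros (the co-expression fallback).
#'
#' @param records record table with `gene_id` set (see
#'   [map_to_reference()]).
#' @param meta a `meta_pcc` object.
#' @param config a [knn_config()].
#' @return matrix (records x K values) with rownames = protein ids.
#' @export
knn_score_table <- function(records, meta, config) {
  out <- matrix(0, nrow = nrow(records), ncol = length(config$k_percent),
                dimnames = list(records$id,
                                sprintf("K%g", config$k_percent)))
  for (i in seq_len(nrow(records))) {
    g <- records$gene_id[i]
    if (!is.na(g) && g %in% meta$genes)
      out[i, ] <- knn_scores(g, meta, config)
  }
  out
}

#' Attach reference-gene mappings to records
#'
#' Joins a protein-to-reference-gene best-hit table (produced
#' externally, e.g. by a BLAST best-hit search at an e-value cutoff)
#' onto the records. Proteins without a table entry keep `gene_id`
#' absent and receive the five-zero co-expression block downstream.
#'
#' @param records record table.
#' @param mapping a `data.frame` with columns `protein_id` and
#'   `gene_id`, or a path to a 2-column delimited file.
#' @return the record table with `gene_id` filled in where mapped.
#' @export
map_to_reference <- function(records, mapping) {
  if (is.character(mapping))
    mapping <- read.table(mapping, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("protein_id", "gene_id"))
  dup <- mapping[duplicated(mapping$protein_id) |
                   duplicated(mapping$protein_id, fromLast = TRUE), ,
                 drop = FALSE]
  if (nrow(dup) > 0) {
    conf <- tapply(dup$gene_id, dup$protein_id,
                   function(g) length(unique(g)) > 1)
    if (any(conf))
      stop("conflicting gene_id mappings for: ",
           paste(names(conf)[conf], collapse = ", "))
    mapping <- mapping[!duplicated(mapping$protein_id), , drop = FALSE]
  }
  m <- match(records$id, mapping$protein_id)
  records$gene_id[!is.na(m)] <- mapping$gene_id[m[!is.na(m)]]
  records
}

#' Read an expression-dataset manifest
#'
#' The manifest is a tab-delimited file with a header and columns
#' `dataset_id`, `path`, `n_samples`, `logged`; each `path` (resolved
#' relative to the manifest) is a delimited expression matrix whose
#' first column holds gene ids and whose header row holds sample ids.
#' Unlogged datasets are log2-transformed on load.
#'
#' @param path manifest path.
#' @return list of `expression_dataset` objects.
#' @export
read_expression_manifest <- function(path) {
  man <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("dataset_id", "path", "n_samples", "logged")
  if (!all(need %in% names(man)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    tab <- read.table(p, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    ds <- expression_dataset(man$dataset_id[i], as.matrix(tab),
                             logged = isTRUE(as.logical(man$logged[i])))
    if (ds$n_samples != man$n_samples[i])
      stop("manifest sample count mismatch for ", man$dataset_id[i])
    if (!ds$logged) ds <- log2_transform(ds)
    ds
  })
}

#' Meta-PCC matrix from a list of expression datasets
#'
#' Pipeline convenience: [pearson_matrix()] per dataset followed by
#' [meta_combine()].
#'
#' @param datasets list of `expression_dataset` objects (log scale).
#' @return a `meta_pcc` object.
#' @export
meta_pcc_from_datasets <- function(datasets) {
  meta_combine(lapply(datasets, pearson_matrix),
               vapply(datasets, function(d) d$n_samples, numeric(1)))
}
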