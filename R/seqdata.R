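#' Read a protein FASTA file into a record table
#'
#' Parses a FASTA file into the package's standard record table: one row
#' per entry with columns `id` (first whitespace-delimited token of the
#' header), `sequence` (uppercased), `label` (`"unknown"` unless
#' attached later, see [read_labels()]), `species` and `gene_id`
#' (both `NA` until set).
#'
#' Sequences may contain the 20 standard residues plus the ambiguity
#' codes X, B, Z, U, O. Anything else, an empty sequence, a duplicated
#' id, or sequence data before the first header is an error naming the
#' offending entry.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` of protein records.
#' @seealso [filter_min_length()], [reduce_redundancy()],
#'   [partition_dataset()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  nonblank <- raw[nzchar(trimws(raw))]
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(nonblank[1], ">"))
    stop("malformed FASTA (sequence line before any header): ",
         substr(nonblank[1], 1, 40))
  # validate raw entries first: Biostrings silently drops invalid codes
  hdr_ix <- which(startsWith(raw, ">"))
  raw_ids <- vapply(strsplit(sub("^>", "", raw[hdr_ix]), "\\s+"),
                    `[`, character(1), 1L)
  allowed <- c(AA_ALPHABET, AA_AMBIGUOUS)
  bounds <- c(hdr_ix, length(raw) + 1L)
  for (e in seq_along(hdr_ix)) {
    body <- raw[seq(bounds[e] + 1L, bounds[e + 1L] - 1L)]
    body <- toupper(gsub("\\s", "", paste(body, collapse = "")))
    if (!nzchar(body))
      stop("empty sequence for entry '", raw_ids[e], "'")
    bad <- setdiff(unique(strsplit(body, "")[[1]]), allowed)
    if (length(bad) > 0)
      stop("invalid residue(s) ", paste(bad, collapse = ","),
           " in entry '", raw_ids[e], "'")
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), label = "unknown",
             species = NA_character_, gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Attach labels to a record table
#'
#' Reads a 2-column delimited file (id, label) and sets `label` on the
#' matching records. Labels must be `positive`, `negative` or
#' `unknown`.
#'
#' @param records record table from [read_fasta()].
#' @param path path to a tab- or whitespace-delimited 2-column file.
#' @return the record table with `label` filled in.
#' @export
read_labels <- function(records, path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "label"))
  bad <- setdiff(unique(tab$label), c("positive", "negative", "unknown"))
  if (length(bad) > 0)
    stop("invalid label value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label file")
  m <- match(records$id, tab$id)
  records$label[!is.na(m)] <- tab$label[m[!is.na(m)]]
  records
}

#' Drop sequences shorter than a minimum length
#'
#' Sequences with fewer than `min_len` residues are excluded (the
#' default mirrors the common 50-residue cutoff for targeting-signal
#' analysis). Order is preserved; the operation is idempotent.
#'
#' @param records record table.
#' @param min_len minimum sequence length to keep (>= 1).
#' @return the filtered record table.
#' @export
filter_min_length <- function(records, min_len = 50L) {
  stopifnot(min_len >= 1)
  records[nchar(records$sequence) >= min_len, , drop = FALSE]
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

# Estimated pairwise identity: shared distinct k-mers over the smaller
# distinct k-mer set (containment estimate; robust to repeats).
estimate_identity <- function(a, b, k = 5L) {
  ka <- kmer_set(a, k)
  kb <- kmer_set(b, k)
  denom <- min(length(ka), length(kb))
  if (denom < 1) return(0)
  length(intersect(ka, kb)) / denom
}

#' Reduce sequence redundancy by greedy clustering
#'
#' Greedy longest-first clustering on an estimated pairwise identity
#' (k-mer containment: shared distinct k-mers divided by the size of
#' the smaller distinct k-mer set). Each sequence joins the first existing
#' cluster whose representative it matches at or above
#' `identity_threshold`; representatives are the longest member of each
#' cluster. This is an approximation -- it is not bit-compatible with
#' external clustering tools such as CD-HIT. For fidelity to an
#' external clustering, pass `clusters`, a 2-column table
#' (id, cluster_id); then only representative selection (longest per
#' cluster) is performed.
#'
#' @param records non-empty record table.
#' @param identity_threshold clustering threshold in (0, 1].
#' @param k k-mer size for the identity estimate.
#' @param clusters optional precomputed cluster membership: a
#'   `data.frame` with columns `id` and `cluster_id`, or a path to a
#'   2-column delimited file.
#' @return the representative records, in input order.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.40, k = 5L,
                              clusters = NULL) {
  if (nrow(records) == 0L) stop("no records to cluster")
  if (!is.null(clusters)) {
    if (is.character(clusters))
      clusters <- read.table(clusters, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("id", "cluster_id"))
    m <- match(records$id, clusters$id)
    if (anyNA(m)) stop("cluster table missing id(s): ",
                       paste(records$id[is.na(m)], collapse = ", "))
    cl <- clusters$cluster_id[m]
    keep <- unlist(lapply(split(seq_len(nrow(records)), cl), function(ix) {
      ix[which.max(nchar(records$sequence[ix]))]
    }), use.names = FALSE)
    return(records[sort(keep), , drop = FALSE])
  }
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  ord <- order(-nchar(records$sequence), seq_len(nrow(records)))
  rep_idx <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (r in rep_idx) {
      if (estimate_identity(records$sequence[i], records$sequence[r],
                            k = k) >= identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) rep_idx <- c(rep_idx, i)
  }
  records[sort(rep_idx), , drop = FALSE]
}

#' Partition records into training / specificity / test sets
#'
#' Randomly (but reproducibly, given `seed`) selects a class-balanced
#' training set, a negative-only specificity-estimation set, and a
#' balanced independent test set, all pairwise disjoint by id. The
#' specificity set feeds [build_calibration()]: the empirical score
#' distribution of held-out negatives converts raw classifier scores
#' into estimated specificity levels.
#'
#' @param records labeled record table.
#' @param n_train_per_class training records drawn from each class.
#' @param n_spec_neg negatives reserved for specificity estimation.
#' @param n_test_per_class test records drawn from each class.
#' @param seed integer seed.
#' @return an object of class `dataset_partition`: a list with
#'   components `training`, `specificity_set` and `test` (record
#'   tables).
#' @export
partition_dataset <- function(records, n_train_per_class, n_spec_neg,
                              n_test_per_class, seed = 1L) {
  pos <- records$id[records$label == "positive"]
  neg <- records$id[records$label == "negative"]
  need_pos <- n_train_per_class + n_test_per_class
  need_neg <- n_train_per_class + n_spec_neg + n_test_per_class
  if (length(pos) < need_pos)
    stop("insufficient positives: need ", need_pos, ", have ", length(pos),
         " (short by ", need_pos - length(pos), ")")
  if (length(neg) < need_neg)
    stop("insufficient negatives: need ", need_neg, ", have ", length(neg),
         " (short by ", need_neg - length(neg), ")")
  ids <- with_seed(seed, {
    p <- sample(pos)
    n <- sample(neg)
    list(train = c(p[seq_len(n_train_per_class)],
                   n[seq_len(n_train_per_class)]),
         spec = n[n_train_per_class + seq_len(n_spec_neg)],
         test = c(p[n_train_per_class + seq_len(n_test_per_class)],
                  n[n_train_per_class + n_spec_neg +
                      seq_len(n_test_per_class)]))
  })
  take <- function(sel) records[match(sel, records$id), , drop = FALSE]
  structure(list(training = take(ids$train),
                 specificity_set = take(ids$spec),
                 test = take(ids$test),
                 seed = seed),
            class = "dataset_partition")
}

#' @export
print.dataset_partition <- function(x, ...) {
  cat("Dataset partition (seed", x$seed, ")\n")
  cat("  training:        ", nrow(x$training), "records (",
      sum(x$training$label == "positive"), "positive /",
      sum(x$training$label == "negative"), "negative )\n")
  cat("  specificity set: ", nrow(x$specificity_set), "negatives\n")
  cat("  test:            ", nrow(x$test), "records\n")
  invisible(x)
}
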