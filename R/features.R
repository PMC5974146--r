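FEATURE_BLOCKS <- c("AAFreq.NT", "PSSM.NT", "PSSM", "Coexpr")

#' Feature configuration
#'
#' Controls which of the four feature blocks are computed and the
#' N-terminal window length shared by the frequency and N-terminal
#' PSSM blocks.
#'
#' @param nterm_window N-terminal window length in residues (5-50;
#'   default 22, the typical scale of a mitochondrial pre-sequence).
#' @param blocks subset of `"AAFreq.NT"`, `"PSSM.NT"`, `"PSSM"`,
#'   `"Coexpr"`; blocks are always assembled in this fixed order.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(nterm_window = 22L, blocks = FEATURE_BLOCKS) {
  if (nterm_window < 5 || nterm_window > 50)
    stop("nterm_window must be in [5, 50]")
  blocks <- FEATURE_BLOCKS[FEATURE_BLOCKS %in% blocks]
  if (length(blocks) == 0L) stop("at least one feature block required")
  structure(list(nterm_window = as.integer(nterm_window), blocks = blocks),
            class = "feature_config")
}

block_lengths <- function(config) {
  len <- c(AAFreq.NT = 20L,
           PSSM.NT = 20L * config$nterm_window,
           PSSM = 400L,
           Coexpr = 5L)
  len[config$blocks]
}

#' Amino-acid frequency over an N-terminal window
#'
#' Fraction of each of the 20 standard residues among the first
#' `window` residues (the whole sequence if it is shorter, or if
#' `window = Inf`). Ambiguity codes are excluded from the denominator,
#' so the 20 entries always sum to one.
#'
#' @param sequence amino-acid string.
#' @param window window length in residues, or `Inf` for the whole
#'   sequence.
#' @return named numeric vector of length 20 summing to 1.
#' @export
aa_frequency <- function(sequence, window = 22L) {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (is.finite(window)) res <- res[seq_len(min(window, length(res)))]
  res <- res[res %in% AA_ALPHABET]
  if (length(res) == 0L)
    stop("window contains no standard residues")
  counts <- table(factor(res, levels = AA_ALPHABET))
  setNames(as.vector(counts) / length(res), AA_ALPHABET)
}

#' N-terminal PSSM feature
#'
#' Concatenates the first `L` rows of a scaled profile in
#' position-major order (position p, alphabet index a maps to flat
#' index `(p - 1) * 20 + a`). Sequences shorter than `L` are
#' zero-padded at the missing positions.
#'
#' @param profile a scaled `profile_matrix`.
#' @param L window length (5-50).
#' @return numeric vector of length `20 * L`.
#' @export
nterm_profile_feature <- function(profile, L = 22L) {
  stopifnot(inherits(profile, "profile_matrix"))
  if (!profile$scaled) stop("profile must be scaled first")
  if (L < 5 || L > 50) stop("window length must be in [5, 50]")
  n <- nrow(profile$mat)
  out <- matrix(0, nrow = L, ncol = 20L)
  use <- min(L, n)
  if (use > 0) out[seq_len(use), ] <- profile$mat[seq_len(use), , drop = FALSE]
  as.vector(t(out))
}

#' Global PSSM feature (profile average pooling)
#'
#' For each of the 20 residue types, the mean of all scaled profile
#' rows at positions where the sequence carries that residue; types
#' absent from the sequence give a zero row. The 20 mean rows are
#' concatenated in alphabet order, yielding a length-invariant 400-long
#' "generalised amino-acid frequency" of the profile.
#'
#' @param profile a scaled `profile_matrix` with one row per residue of
#'   `sequence`.
#' @param sequence the protein sequence.
#' @return numeric vector of length 400.
#' @export
global_profile_feature <- function(profile, sequence) {
  stopifnot(inherits(profile, "profile_matrix"))
  if (!profile$scaled) stop("profile must be scaled first")
  res <- strsplit(toupper(sequence), "")[[1]]
  if (nrow(profile$mat) != length(res))
    stop("profile row count does not match sequence length")
  out <- matrix(0, nrow = 20L, ncol = 20L,
                dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (a in AA_ALPHABET) {
    ix <- which(res == a)
    if (length(ix) > 0)
      out[a, ] <- colMeans(profile$mat[ix, , drop = FALSE])
  }
  as.vector(t(out))
}

#' Assemble the feature vector for one protein
#'
#' Concatenates the enabled blocks in the fixed order AAFreq.NT,
#' PSSM.NT, PSSM, Coexpr and records the block layout (name, offset,
#' length). With the default configuration the full vector has length
#' 20 + 440 + 400 + 5 = 865. A protein without a co-expression mapping
#' contributes five zeros to the Coexpr block.
#'
#' @param record one-row record table (or a list with `id` and
#'   `sequence`).
#' @param profile a `profile_matrix` for the record (scaled or
#'   unscaled; unscaled profiles are scaled on the fly). Required when
#'   a PSSM block is enabled.
#' @param knn numeric 5-vector of co-expression KNN scores, or `NULL`
#'   for the five-zero fallback.
#' @param config a [feature_config()].
#' @return object of class `feature_vector`: list with `protein_id`,
#'   `values` and `layout` (data.frame block/offset/length).
#' @export
assemble_features <- function(record, profile = NULL, knn = NULL,
                              config = feature_config()) {
  id <- record$id
  sequence <- record$sequence
  needs_profile <- any(c("PSSM.NT", "PSSM") %in% config$blocks)
  if (needs_profile && is.null(profile))
    stop("PSSM blocks enabled but no profile supplied for '", id, "'")
  if (!is.null(profile) && !profile$scaled) profile <- scale_profile(profile)
  pieces <- list()
  for (b in config$blocks) {
    pieces[[b]] <- switch(b,
      AAFreq.NT = {
        v <- aa_frequency(sequence, config$nterm_window)
        unname(v)
      },
      PSSM.NT = nterm_profile_feature(profile, config$nterm_window),
      PSSM = global_profile_feature(profile, sequence),
      Coexpr = {
        if (is.null(knn)) rep(0, 5)
        else {
          if (length(knn) != 5L) stop("knn must be a 5-vector")
          as.numeric(knn)
        }
      })
  }
  len <- vapply(pieces, length, integer(1))
  layout <- data.frame(block = names(pieces),
                       offset = cumsum(c(0L, unname(len)[-length(len)])),
                       length = unname(len),
                       stringsAsFactors = FALSE)
  structure(list(protein_id = id,
                 values = unlist(pieces, use.names = FALSE),
                 layout = layout),
            class = "feature_vector")
}

#' Build a feature matrix for a set of records
#'
#' Applies [assemble_features()] to every record. Records without an
#' entry in `profiles` fall back to the BLOSUM62 substitution profile
#' (flagged in the `profile_source` attribute); records without a row
#' in `knn` get the five-zero co-expression block.
#'
#' @param records record table.
#' @param profiles named list of `profile_matrix` objects (names =
#'   protein ids), or `NULL` to use the substitution fallback for all.
#' @param knn matrix of KNN scores with rownames = protein ids (5
#'   columns), or `NULL`.
#' @param config a [feature_config()].
#' @return numeric matrix (records x features) with rownames = ids and
#'   attributes `layout` (block layout data.frame) and
#'   `profile_source` (per-record character vector).
#' @export
build_feature_matrix <- function(records, profiles = NULL, knn = NULL,
                                 config = feature_config()) {
  n <- nrow(records)
  rows <- vector("list", n)
  src <- character(n)
  layout <- NULL
  for (i in seq_len(n)) {
    id <- records$id[i]
    prof <- if (!is.null(profiles) && !is.null(profiles[[id]]))
      profiles[[id]]
    else if (any(c("PSSM.NT", "PSSM") %in% config$blocks))
      substitution_fallback_profile(records$sequence[i], id)
    else NULL
    src[i] <- if (is.null(prof)) NA_character_ else prof$source
    kv <- if (!is.null(knn) && id %in% rownames(knn))
      as.numeric(knn[id, ]) else NULL
    fv <- assemble_features(records[i, ], profile = prof, knn = kv,
                            config = config)
    rows[[i]] <- fv$values
    layout <- fv$layout
  }
  x <- do.call(rbind, rows)
  rownames(x) <- records$id
  attr(x, "layout") <- layout
  attr(x, "profile_source") <- setNames(src, records$id)
  x
}

layout_fingerprint <- function(layout) {
  paste(sprintf("%s:%d:%d", layout$block, layout$offset, layout$length),
        collapse = "|")
}

#' Write / read a feature matrix as delimited text
#'
#' The header row names each column `block:index` so the block layout
#' survives the round trip; values are written with 17 significant
#' digits, making write-then-read lossless.
#'
#' @param x feature matrix from [build_feature_matrix()].
#' @param path output (input) file path.
#' @return `read_features` returns the feature matrix with its `layout`
#'   attribute reconstructed.
#' @export
write_features <- function(x, path) {
  layout <- attr(x, "layout")
  if (is.null(layout)) stop("feature matrix has no layout attribute")
  cols <- unlist(mapply(function(b, l) sprintf("%s:%d", b, seq_len(l)),
                        layout$block, layout$length, SIMPLIFY = FALSE))
  fm <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  out <- cbind(id = rownames(x), fm)
  colnames(out) <- c("id", cols)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- tab$id
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- ids
  blocks <- sub(":\\d+$", "", colnames(x))
  rb <- rle(blocks)
  layout <- data.frame(block = rb$values,
                       offset = cumsum(c(0L, rb$lengths[-length(rb$lengths)])),
                       length = rb$lengths,
                       stringsAsFactors = FALSE)
  attr(x, "layout") <- layout
  x
}
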