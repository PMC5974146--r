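#' Construct a per-position sequence profile
#'
#' A profile holds one row of 20 scores per sequence position, columns
#' in the package's fixed alphabet order (ACDEFGHIKLMNPQRSTVWY).
#'
#' @param protein_id protein identifier.
#' @param mat numeric matrix, rows = positions, 20 columns.
#' @param scaled has the matrix been min-max scaled to \[-1, 1\]?
#' @param source `"psiblast_ascii"` or `"substitution_fallback"`.
#' @return an object of class `profile_matrix`.
#' @export
profile_matrix <- function(protein_id, mat,
                           scaled = FALSE,
                           source = c("psiblast_ascii",
                                      "substitution_fallback")) {
  source <- match.arg(source)
  mat <- as.matrix(mat)
  if (ncol(mat) != 20L) stop("profile must have 20 columns")
  colnames(mat) <- AA_ALPHABET
  if (scaled && nrow(mat) > 0 &&
      (min(mat) < -1 - 1e-9 || max(mat) > 1 + 1e-9))
    stop("scaled profile entries must lie in [-1, 1]")
  structure(list(protein_id = protein_id, mat = mat,
                 scaled = scaled, source = source),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Profile for", x$protein_id, ":", nrow(x$mat), "positions x 20,",
      if (x$scaled) "scaled," else "unscaled,", "source =", x$source, "\n")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard ASCII position-specific scoring matrix layout
#' produced by PSI-BLAST (`-Q` / blastpgp `-Q`): a header line naming
#' the residue column order, then one row per position with the
#' position index, the query residue, and 20 integer log-odds scores.
#' Columns are remapped into the fixed alphabet order and the residue
#' column is cross-checked against `sequence`.
#'
#' @param path path to the ASCII PSSM file.
#' @param sequence the protein sequence the profile belongs to.
#' @param protein_id identifier stored on the profile (defaults to the
#'   file name stem).
#' @return an unscaled `profile_matrix`.
#' @export
parse_pssm <- function(path, sequence,
                       protein_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  # header: first line whose tokens are >= 20 single residue letters
  hdr <- NULL
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) >= 20 && all(nchar(tk) == 1L) &&
        all(tk[1:20] %in% AA_ALPHABET)) {
      hdr <- i
      break
    }
  }
  if (is.null(hdr)) stop("no residue-order header line found in ", path)
  file_order <- toks[[hdr]][1:20]
  if (length(unique(file_order)) != 20L)
    stop("header residue order is not a permutation of the alphabet in ",
         path)
  rows <- list()
  res <- character(0)
  for (i in (hdr + 1):length(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 22) break  # blank line / trailing statistics
    if (is.na(suppressWarnings(as.integer(tk[1])))) break
    v <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(v)) stop("non-numeric score in PSSM row ", tk[1], " of ", path)
    rows[[length(rows) + 1L]] <- v
    res <- c(res, toupper(tk[2]))
  }
  if (length(rows) == 0L) stop("no PSSM rows found in ", path)
  mat <- do.call(rbind, rows)
  colnames(mat) <- file_order
  mat <- mat[, AA_ALPHABET, drop = FALSE]
  seqres <- strsplit(toupper(sequence), "")[[1]]
  if (nrow(mat) != length(seqres))
    stop("PSSM has ", nrow(mat), " rows but sequence has ",
         length(seqres), " residues (", protein_id, ")")
  mism <- which(res != seqres)
  if (length(mism) > 0)
    stop("PSSM residue column disagrees with sequence at position(s) ",
         paste(head(mism, 5), collapse = ","), " (", protein_id, ")")
  profile_matrix(protein_id, mat, scaled = FALSE, source = "psiblast_ascii")
}

#' Scale a profile linearly to \[-1, 1\]
#'
#' Applies the per-protein affine map
#' `x -> 2 * (x - min) / (max - min) - 1` using the matrix-wide minimum
#' and maximum. A constant matrix maps to all zeros. Scaling is
#' monotone, and rescaling an already full-range matrix is the
#' identity.
#'
#' @param profile an unscaled `profile_matrix`.
#' @return the scaled `profile_matrix`.
#' @export
scale_profile <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  if (profile$scaled) stop("profile is already scaled")
  m <- profile$mat
  lo <- min(m)
  hi <- max(m)
  m <- if (hi > lo) 2 * (m - lo) / (hi - lo) - 1 else m * 0
  profile_matrix(profile$protein_id, m, scaled = TRUE,
                 source = profile$source)
}

blosum62_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

#' Substitution-matrix fallback profile
#'
#' Builds a per-position profile from fixed BLOSUM62 log-odds rows
#' (row i = the BLOSUM62 row of residue i; ambiguity codes give a zero
#' row). This enables database-free operation when no evolutionary
#' profile is available; the `source` flag
#' (`"substitution_fallback"`) is propagated so downstream outputs can
#' report that predictions did not use a real sequence profile.
#'
#' @param sequence amino-acid string.
#' @param protein_id identifier stored on the profile.
#' @return an unscaled `profile_matrix`.
#' @export
substitution_fallback_profile <- function(sequence, protein_id = "query") {
  res <- strsplit(toupper(sequence), "")[[1]]
  B <- blosum62_rows()
  mat <- matrix(0, nrow = length(res), ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET))
  std <- res %in% AA_ALPHABET
  mat[std, ] <- B[res[std], , drop = FALSE]
  profile_matrix(protein_id, mat, scaled = FALSE,
                 source = "substitution_fallback")
}
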