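#' Build a specificity calibration table from negative scores
#'
#' Stores the empirical score distribution of a held-out negative
#' reference set (sorted descending). Thresholding this distribution
#' converts a raw classifier score into an estimated specificity: the
#' fraction of reference negatives that would *not* be called
#' positive at that threshold.
#'
#' @param scores classifier scores on specificity-set negatives.
#' @return object of class `specificity_calibration`.
#' @export
build_calibration <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) stop("no negative scores to calibrate on")
  if (anyNA(scores)) stop("NA scores in calibration set")
  if (length(scores) < 100L)
    warning("only ", length(scores),
            " negative scores; specificity estimates will be coarse")
  structure(list(scores = sort(scores, decreasing = TRUE),
                 n_negatives = length(scores)),
            class = "specificity_calibration")
}

#' @export
print.specificity_calibration <- function(x, ...) {
  cat("Specificity calibration on", x$n_negatives, "negative scores\n")
  for (lv in c(0.90, 0.95, 0.99))
    cat(sprintf("  level %.2f -> threshold %g\n", lv,
                threshold_for_specificity(x, lv)))
  invisible(x)
}

#' Decision threshold for a requested specificity level
#'
#' Returns the smallest threshold `t` such that the fraction of
#' calibration negatives scoring at or above `t` is at most
#' `1 - level`; the empirical specificity at `t` on the calibration
#' set is therefore always >= `level`. Ties among negative scores are
#' handled conservatively (all tied values count as above the
#' threshold). If no score qualifies, a threshold strictly above the
#' maximum negative score is returned.
#'
#' @param table a `specificity_calibration`.
#' @param level requested specificity in (0, 1).
#' @return the decision threshold (scores >= threshold are called
#'   positive, see [classify_scores()]).
#' @export
threshold_for_specificity <- function(table, level) {
  stopifnot(inherits(table, "specificity_calibration"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n <- table$n_negatives
  allowed <- floor((1 - level) * n)  # max negatives at/above threshold
  r <- rle(table$scores)             # descending distinct values
  cnt <- cumsum(r$lengths)
  ok <- which(cnt <= allowed)
  if (length(ok) > 0) {
    r$values[max(ok)]
  } else {
    mx <- r$values[1]
    mx + max(1e-8, abs(mx) * 1e-8)
  }
}

#' Threshold table for standard specificity levels
#'
#' @param table a `specificity_calibration`.
#' @param levels specificity levels (default 0.90, 0.95, 0.99).
#' @return data.frame with columns `level` and `threshold`.
#' @export
calibration_table <- function(table, levels = c(0.90, 0.95, 0.99)) {
  data.frame(level = levels,
             threshold = vapply(levels, threshold_for_specificity,
                                numeric(1), table = table))
}

#' Binary calls from scores and a threshold
#'
#' Scores at or above the threshold are called positive.
#'
#' @param scores numeric score vector.
#' @param threshold decision threshold.
#' @return logical vector of positive calls.
#' @export
classify_scores <- function(scores, threshold) {
  scores >= threshold
}
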