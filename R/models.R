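#' Stratified k-fold assignment
#'
#' Shuffles each class independently (reproducibly for a fixed seed)
#' and deals it round-robin into `k` folds, so per-fold class counts
#' differ by at most one from the exact quota.
#'
#' @param labels vector of labels (`positive`/`negative` or logical).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per example.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  y <- as_binary_label(labels)
  counts <- table(y)
  if (k > min(counts))
    stop("k = ", k, " exceeds the smallest class count (", min(counts), ")")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      ix <- sample(which(y == cl))
      fold[ix] <- rep(seq_len(k), length.out = length(ix))
    }
  })
  fold
}

fit_svm <- function(x, y, cost, gamma) {
  if (!all(is.finite(x))) stop("non-finite feature values")
  yb <- as_binary_label(y)
  if (nlevels(droplevels(yb)) < 2L)
    stop("training data contains a single class")
  e1071::svm(x, yb, kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE, tolerance = 1e-4)
}

svm_decision <- function(fit, x) {
  p <- predict(fit, x, decision.values = TRUE)
  d <- attr(p, "decision.values")
  # libsvm orients decision values toward the first factor level
  # ("positive" by construction); flip defensively if not.
  if (colnames(d)[1] == "negative/positive") -as.numeric(d)
  else as.numeric(d)
}

#' Grid search for RBF-SVM cost and gamma
#'
#' Evaluates every (cost, gamma) grid point by mean stratified k-fold
#' cross-validated AUC and returns the maximiser; ties break toward
#' the smaller cost, then the smaller gamma. The default grids are the
#' seven cost decades 1e-3..1e3 and the eleven gamma decades
#' 1e-5..1e5 (77 candidates).
#'
#' @param x feature matrix.
#' @param y labels (balanced recommended).
#' @param cost_grid,gamma_grid candidate values.
#' @param k folds.
#' @param seed integer seed (fold assignment).
#' @return list with `cost`, `gamma`, `auc` and the full results
#'   `table` (data.frame cost/gamma/mean_auc).
#' @export
grid_search_svm <- function(x, y, cost_grid = 10^(-3:3),
                            gamma_grid = 10^(-5:5), k = 10L, seed = 1L) {
  fold <- stratified_kfold(y, k = k, seed = seed)
  grid <- expand.grid(gamma = sort(gamma_grid), cost = sort(cost_grid))
  grid <- grid[order(grid$cost, grid$gamma), ]
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(k)
    for (i in seq_len(k)) {
      tr <- fold != i
      fit <- fit_svm(x[tr, , drop = FALSE], y[tr],
                     cost = grid$cost[g], gamma = grid$gamma[g])
      aucs[i] <- auc_rank(y[fold == i],
                          svm_decision(fit, x[fold == i, , drop = FALSE]))
    }
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)  # first maximum = smallest cost then gamma
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       auc = mean_auc[best],
       table = data.frame(cost = grid$cost, gamma = grid$gamma,
                          mean_auc = mean_auc))
}

#' Train a mitochondrial-targeting classifier
#'
#' Fits either a radial-basis SVM on the full training set, or an
#' ensemble of maxout/dropout networks: the training set is split into
#' `n_members` stratified folds and, for each rotation, one fold is
#' reserved for validation-based snapshot selection while the
#' remaining folds train a member network; the ensemble prediction is
#' the mean of the members' positive-class softmax outputs.
#'
#' The feature layout of `x` (see [build_feature_matrix()]) is
#' fingerprinted; `predict` refuses feature matrices built under a
#' different layout.
#'
#' @param x feature matrix (rows = proteins), ideally from
#'   [build_feature_matrix()].
#' @param y labels (`positive`/`negative` or logical).
#' @param method `"svm"` or `"dnn"`.
#' @param cost,gamma SVM hyperparameters (defaults 10 and 0.1; tune
#'   with [grid_search_svm()]).
#' @param dnn a [dnn_config()] for the network members.
#' @param n_members ensemble size for `method = "dnn"`.
#' @param seed integer seed (fold assignment and member seeds).
#' @return object of class `mito_model`.
#' @export
mito_train <- function(x, y, method = c("svm", "dnn"),
                       cost = 10, gamma = 0.1, dnn = dnn_config(),
                       n_members = 10L, seed = 1L) {
  method <- match.arg(method)
  layout <- attr(x, "layout")
  fp <- if (!is.null(layout)) layout_fingerprint(layout) else NULL
  if (method == "svm") {
    fit <- fit_svm(x, y, cost = cost, gamma = gamma)
    members <- list(fit)
    config <- list(cost = cost, gamma = gamma)
  } else {
    fold <- stratified_kfold(y, k = n_members, seed = seed)
    members <- vector("list", n_members)
    for (i in seq_len(n_members)) {
      cfg <- dnn
      cfg$seed <- seed + i
      val <- fold == i
      members[[i]] <- dnn_train(x[!val, , drop = FALSE], y[!val],
                                x[val, , drop = FALSE], y[val],
                                config = cfg)
    }
    config <- dnn
  }
  structure(list(method = method, members = members,
                 fingerprint = fp, n_features = ncol(x),
                 config = config, seed = seed),
            class = "mito_model")
}

check_compatible <- function(object, newdata) {
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch: model expects ", object$n_features,
         ", got ", ncol(newdata))
  layout <- attr(newdata, "layout")
  if (!is.null(object$fingerprint) && !is.null(layout) &&
      layout_fingerprint(layout) != object$fingerprint)
    stop("feature layout fingerprint mismatch: refusing to predict")
  invisible(TRUE)
}

#' Predict scores from a fitted classifier
#'
#' SVM models return real decision values (larger = more
#' mitochondrial-like); network ensembles return mean positive-class
#' probabilities in \[0, 1\]. Both are usable for ROC ranking and for
#' specificity calibration via [build_calibration()].
#'
#' @param object a `mito_model`.
#' @param newdata feature matrix with the training layout.
#' @param ... unused.
#' @return numeric score vector named by rownames of `newdata`.
#' @export
predict.mito_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L) return(numeric(0))
  check_compatible(object, newdata)
  scores <- if (object$method == "svm") {
    svm_decision(object$members[[1]], newdata)
  } else {
    rowMeans(vapply(object$members, dnn_predict, numeric(nrow(newdata)),
                    x = newdata))
  }
  setNames(scores, rownames(newdata))
}

#' @export
print.mito_model <- function(x, ...) {
  cat("Mitochondrial targeting classifier (", x$method, ")\n", sep = "")
  cat("  members:", length(x$members), " features:", x$n_features, "\n")
  if (x$method == "svm")
    cat("  cost =", x$config$cost, " gamma =", x$config$gamma, "\n")
  else
    cat("  hidden:", paste(x$config$hidden, collapse = "-"),
        " pieces:", x$config$pieces, " dropout:", x$config$dropout, "\n")
  invisible(x)
}

#' @export
summary.mito_model <- function(object, ...) {
  print(object)
  if (object$method == "dnn") {
    va <- vapply(object$members, `[[`, numeric(1), "best_val_auc")
    be <- vapply(object$members, `[[`, numeric(1), "best_epoch")
    cat("  member validation AUCs:",
        paste(round(va, 3), collapse = " "), "\n")
    cat("  member best epochs:    ", paste(be, collapse = " "), "\n")
  } else {
    cat("  support vectors:", nrow(object$members[[1]]$SV), "\n")
  }
  invisible(object)
}

#' Stratified cross-validation of a classifier
#'
#' Runs the 10-fold protocol: for the SVM, each rotation trains on
#' nine folds and scores the held-out fold; for the network, each
#' rotation holds out one fold for testing and the next fold (cyclic)
#' for validation-based snapshot selection, training on the remaining
#' eight, so every fold serves as validation or test exactly once.
#'
#' @inheritParams mito_train
#' @param k number of folds.
#' @return object of class `mito_cv`: per-example held-out `scores`
#'   and `labels`, the fold assignment, `per_fold_auc` and `mean_auc`.
#' @export
mito_cv <- function(x, y, method = c("svm", "dnn"),
                    cost = 10, gamma = 0.1, dnn = dnn_config(),
                    k = 10L, seed = 1L) {
  method <- match.arg(method)
  fold <- stratified_kfold(y, k = k, seed = seed)
  scores <- rep(NA_real_, nrow(x))
  per_fold <- numeric(k)
  for (i in seq_len(k)) {
    test <- fold == i
    if (method == "svm") {
      fit <- fit_svm(x[!test, , drop = FALSE], y[!test],
                     cost = cost, gamma = gamma)
      sc <- svm_decision(fit, x[test, , drop = FALSE])
    } else {
      val <- fold == (i %% k) + 1L
      train <- !test & !val
      cfg <- dnn
      cfg$seed <- seed + i
      net <- dnn_train(x[train, , drop = FALSE], y[train],
                       x[val, , drop = FALSE], y[val], config = cfg)
      sc <- dnn_predict(net, x[test, , drop = FALSE])
    }
    scores[test] <- sc
    per_fold[i] <- auc_rank(y[test], sc)
  }
  structure(list(method = method, fold = fold, scores = scores,
                 labels = as_binary_label(y), per_fold_auc = per_fold,
                 mean_auc = mean(per_fold), k = k, seed = seed),
            class = "mito_cv")
}

#' @export
print.mito_cv <- function(x, ...) {
  cat("Stratified ", x$k, "-fold cross-validation (", x$method, ")\n",
      sep = "")
  cat("  per-fold AUC:", paste(round(x$per_fold_auc, 3), collapse = " "),
      "\n")
  cat("  mean AUC:", round(x$mean_auc, 4), "\n")
  invisible(x)
}

#' Save / load a model bundle
#'
#' Serialises the model with its configuration and feature-layout
#' fingerprint to a single file.
#'
#' @param model a `mito_model`.
#' @param path file path.
#' @return `mito_load` returns the `mito_model`.
#' @export
mito_save <- function(model, path) {
  stopifnot(inherits(model, "mito_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname mito_save
#' @export
mito_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mito_model"))
  model
}
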