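#' Feed-forward maxout/dropout network configuration
#'
#' Architecture and training schedule for the network classifier:
#' maxout hidden units (max over `pieces` linear pieces), dropout on
#' every hidden layer, a 2-way softmax output, and minibatch SGD with
#' momentum rising linearly between its two endpoints over the epochs.
#' The default architecture is three hidden layers of 500, 500 and 300
#' units with 5 maxout pieces, dropout 0.5, learning rate 0.01,
#' momentum 0.5 rising to 0.7, at most 250 epochs and minibatches of
#' 100; hidden sizes and the epoch cap are configurable so the model
#' can also run at desk scale.
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param pieces maxout pieces per hidden unit.
#' @param dropout dropout probability per hidden layer, in \[0, 1).
#' @param learning_rate SGD learning rate.
#' @param momentum length-2 numeric: initial and final momentum.
#' @param epochs epoch cap (>= 1).
#' @param batch_size minibatch size.
#' @param seed integer seed driving initialisation, shuffling and
#'   dropout masks.
#' @return object of class `dnn_config`.
#' @export
dnn_config <- function(hidden = c(500L, 500L, 300L), pieces = 5L,
                       dropout = 0.5, learning_rate = 0.01,
                       momentum = c(0.5, 0.7), epochs = 250L,
                       batch_size = 100L, seed = 1L) {
  if (length(hidden) < 1L) stop("need at least one hidden layer")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (epochs < 1L) stop("epoch cap must be >= 1")
  structure(list(hidden = as.integer(hidden), pieces = as.integer(pieces),
                 dropout = dropout, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "dnn_config")
}

# Forward pass. Hidden layer l: Z = A W_l + b_l with columns grouped
# per unit (unit u, piece p -> column (u-1)*pieces + p); maxout takes
# the per-unit max. train=TRUE applies inverted dropout with the given
# masks so prediction needs no rescaling.
dnn_forward <- function(net, X, train = FALSE, masks = NULL) {
  A <- X
  acts <- list()
  argmx <- list()
  m <- net$config$pieces
  for (l in seq_along(net$W)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    h <- length(net$b[[l]]) / m
    Amax <- Z[, seq(1, by = m, length.out = h), drop = FALSE]
    idx <- matrix(1L, nrow(Z), h)
    if (m > 1) for (p in 2:m) {
      Zp <- Z[, seq(p, by = m, length.out = h), drop = FALSE]
      upd <- Zp > Amax
      Amax[upd] <- Zp[upd]
      idx[upd] <- p
    }
    if (train && net$config$dropout > 0) {
      Amax <- Amax * masks[[l]]
    }
    acts[[l]] <- list(input = A, max = Amax, idx = idx)
    argmx[[l]] <- idx
    A <- Amax
  }
  S <- sweep(A %*% net$Wout, 2, net$bout, "+")
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P <- P / rowSums(P)
  list(prob = P, acts = acts)
}

new_dnn_weights <- function(d_in, config) {
  m <- config$pieces
  W <- list(); b <- list()
  prev <- d_in
  for (h in config$hidden) {
    W[[length(W) + 1L]] <- matrix(rnorm(prev * h * m, sd = sqrt(2 / prev)),
                                  prev, h * m)
    b[[length(b) + 1L]] <- rep(0, h * m)
    prev <- h
  }
  list(W = W, b = b,
       Wout = matrix(rnorm(prev * 2, sd = sqrt(2 / prev)), prev, 2),
       bout = rep(0, 2))
}

#' Train a single maxout/dropout network
#'
#' Minibatch SGD with momentum on the cross-entropy of a 2-way softmax
#' output. After every epoch the validation AUC is measured and the
#' epoch snapshot with the best validation AUC is kept (training stops
#' early only if validation AUC reaches 1, which no later epoch can
#' improve). If the epoch cap is exhausted the returned model carries
#' `cap_reached = TRUE` -- deep networks can fail to train to a useful
#' validation AUC within the cap on weakly informative feature sets.
#' Fully deterministic for a fixed `config$seed`.
#'
#' @param x training feature matrix.
#' @param y training labels (`positive`/`negative` or logical).
#' @param x_val,y_val validation data, disjoint from training, used for
#'   snapshot selection.
#' @param config a [dnn_config()].
#' @return object of class `maxout_net` with the selected weights,
#'   `best_epoch`, `best_val_auc` and `cap_reached`.
#' @export
dnn_train <- function(x, y, x_val, y_val, config = dnn_config()) {
  yb <- as_binary_label(y) == "positive"
  if (!all(is.finite(x))) stop("non-finite feature values")
  n <- nrow(x)
  Y <- cbind(as.numeric(yb), as.numeric(!yb))  # col 1 = positive
  m <- config$pieces
  with_seed(config$seed, {
    w <- new_dnn_weights(ncol(x), config)
    net <- list(W = w$W, b = w$b, Wout = w$Wout, bout = w$bout,
                config = config)
    vel <- list(W = lapply(w$W, function(z) z * 0),
                b = lapply(w$b, function(z) z * 0),
                Wout = w$Wout * 0, bout = w$bout * 0)
    best <- list(auc = -Inf, epoch = 0L, net = net)
    E <- config$epochs
    for (epoch in seq_len(E)) {
      mu <- config$momentum[1] +
        (config$momentum[2] - config$momentum[1]) *
        (epoch - 1) / max(E - 1, 1)
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        ix <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- x[ix, , drop = FALSE]
        Yb <- Y[ix, , drop = FALSE]
        B <- nrow(Xb)
        masks <- NULL
        if (config$dropout > 0) {
          keep <- 1 - config$dropout
          masks <- lapply(config$hidden, function(h)
            matrix((runif(B * h) < keep) / keep, B, h))
        }
        fw <- dnn_forward(net, Xb, train = TRUE, masks = masks)
        dS <- (fw$prob - Yb) / B
        gWout <- crossprod(fw$acts[[length(net$W)]]$max, dS)
        gbout <- colSums(dS)
        dA <- dS %*% t(net$Wout)
        gW <- vector("list", length(net$W))
        gb <- vector("list", length(net$W))
        for (l in rev(seq_along(net$W))) {
          a <- fw$acts[[l]]
          if (config$dropout > 0) dA <- dA * masks[[l]]
          h <- ncol(a$idx)
          dZ <- matrix(0, nrow(dA), h * m)
          for (p in seq_len(m)) {
            sel <- (a$idx == p)
            if (any(sel))
              dZ[, seq(p, by = m, length.out = h)] <- dA * sel
          }
          gW[[l]] <- crossprod(a$input, dZ)
          gb[[l]] <- colSums(dZ)
          if (l > 1) dA <- dZ %*% t(net$W[[l]])
        }
        lr <- config$learning_rate
        for (l in seq_along(net$W)) {
          vel$W[[l]] <- mu * vel$W[[l]] - lr * gW[[l]]
          vel$b[[l]] <- mu * vel$b[[l]] - lr * gb[[l]]
          net$W[[l]] <- net$W[[l]] + vel$W[[l]]
          net$b[[l]] <- net$b[[l]] + vel$b[[l]]
        }
        vel$Wout <- mu * vel$Wout - lr * gWout
        vel$bout <- mu * vel$bout - lr * gbout
        net$Wout <- net$Wout + vel$Wout
        net$bout <- net$bout + vel$bout
      }
      val_scores <- dnn_forward(net, x_val)$prob[, 1]
      val_auc <- auc_rank(y_val, val_scores)
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, epoch = epoch, net = net)
      }
      if (best$auc >= 1) break
    }
    out <- best$net
    out$best_epoch <- best$epoch
    out$best_val_auc <- best$auc
    out$cap_reached <- (best$auc < 1) && (epoch == E)
    class(out) <- "maxout_net"
    out
  })
}

#' Positive-class probabilities from a trained network
#'
#' @param net a `maxout_net`.
#' @param x feature matrix.
#' @return numeric vector of softmax positive-class probabilities in
#'   \[0, 1\].
#' @export
dnn_predict <- function(net, x) {
  stopifnot(inherits(net, "maxout_net"))
  dnn_forward(net, x)$prob[, 1]
}

#' @export
print.maxout_net <- function(x, ...) {
  cat("Maxout network:", paste(x$config$hidden, collapse = "-"),
      "hidden units,", x$config$pieces, "pieces, dropout",
      x$config$dropout, "\n")
  cat("  best epoch", x$best_epoch, "(validation AUC",
      round(x$best_val_auc, 4), ")",
      if (x$cap_reached) "[epoch cap reached]" else "", "\n")
  invisible(x)
}
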