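#' Training hyperparameters for the triage classifier
#'
#' The schedule constants reproduce the cyclical learning-rate protocol used
#' to train the literature classifier: an initial learning rate `ilr` of
#' 0.25 decays exponentially at rate `k = 0.05` per epoch within a cycle of
#' `c = 100` epochs; at each new cycle the peak restarts, reduced by the
#' descent coefficient `d = 0.95`. Training runs `n_cycles = 10` cycles
#' (1000 epochs). The network has one hidden layer of 96 rectified linear
#' units feeding 2 independent sigmoid output units.
#'
#' `dropout` is the retention probability of a hidden unit under inverted
#' dropout (kept activations are rescaled by `1/dropout` at train time so
#' the expected activation matches evaluation mode); `dropout = 0` disables
#' dropout entirely. Set `dropout_semantics = "drop"` to read the value as a
#' drop probability instead.
#'
#' @param ilr initial learning rate (> 0).
#' @param k exponential decay rate per epoch (>= 0).
#' @param c cycle length in epochs (>= 1).
#' @param d per-cycle descent coefficient in (0, 1].
#' @param dropout dropout parameter in [0, 1); see Details.
#' @param n_cycles number of cycles (>= 1).
#' @param hidden_units hidden-layer width.
#' @param seed integer seed for weight initialisation and dropout masks.
#' @param dropout_semantics `"keep"` (default) or `"drop"`.
#' @return an object of class `glyco_hyperparams`.
#' @export
nn_hyperparams <- function(ilr = 0.25, k = 0.05, c = 100L, d = 0.95,
                           dropout = 0.7, n_cycles = 10L, hidden_units = 96L,
                           seed = NULL,
                           dropout_semantics = c("keep", "drop")) {
  assert_scalar_number(ilr, "ilr", lower = 0, strict_lower = TRUE)
  assert_scalar_number(k, "k", lower = 0)
  assert_scalar_number(c, "c", lower = 1)
  assert_scalar_number(d, "d", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(dropout, "dropout", lower = 0, upper = 1,
                       strict_upper = TRUE)
  assert_scalar_number(n_cycles, "n_cycles", lower = 1)
  assert_scalar_number(hidden_units, "hidden_units", lower = 1)
  structure(list(ilr = ilr, k = k, c = as.integer(c), d = d,
                 dropout = dropout, n_cycles = as.integer(n_cycles),
                 hidden_units = as.integer(hidden_units), seed = seed,
                 dropout_semantics = match.arg(dropout_semantics)),
            class = "glyco_hyperparams")
}

keep_probability <- function(h) {
  if (h$dropout == 0) return(1)
  if (h$dropout_semantics == "keep") h$dropout else 1 - h$dropout
}

#' Initialise network parameters
#'
#' Scaled uniform initialisation appropriate to ReLU fan-in: weights drawn
#' from U(-r, r) with r = sqrt(6 / fan_in); biases start at zero.
#'
#' @param n_features input dimension (vocabulary size).
#' @param hidden_units hidden-layer width.
#' @param seed optional integer seed.
#' @return an object of class `glyco_params`: `W1` (n_features x hidden),
#'   `b1`, `W2` (hidden x 2), `b2`.
#' @export
nn_init_params <- function(n_features, hidden_units = 96L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r1 <- sqrt(6 / max(n_features, 1))
  r2 <- sqrt(6 / hidden_units)
  structure(list(
    W1 = matrix(stats::runif(n_features * hidden_units, -r1, r1),
                n_features, hidden_units),
    b1 = numeric(hidden_units),
    W2 = matrix(stats::runif(hidden_units * 2L, -r2, r2), hidden_units, 2L),
    b2 = numeric(2L)
  ), class = "glyco_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the triage network
#'
#' `hidden = ReLU(x W1 + b1)`, masked and rescaled by the inverted-dropout
#' rule in train mode; `output = sigmoid(hidden W2 + b2)`. The two output
#' units are independent sigmoids — they are not constrained to sum to 1.
#'
#' @param x numeric matrix (n x n_features) or a single feature vector.
#' @param params a `glyco_params` object.
#' @param mode `"eval"` (default) or `"train"`.
#' @param mask binary vector over hidden units; required in train mode
#'   whenever `keep < 1`.
#' @param keep retention probability used for inverted-dropout scaling.
#' @return list with `P` (n x 2 matrix of output probabilities) and `cache`
#'   (activations needed by [nn_backward()]).
#' @export
nn_forward <- function(x, params, mode = c("eval", "train"), mask = NULL,
                       keep = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(params$W1))
    stop("feature dimension mismatch: got ", ncol(x), ", expected ",
         nrow(params$W1), call. = FALSE)
  if (mode == "train" && keep < 1 && is.null(mask))
    stop("train mode with keep < 1 requires a dropout mask", call. = FALSE)
  Z1 <- sweep(x %*% params$W1, 2L, params$b1, `+`)
  H <- pmax(Z1, 0)
  if (mode == "train" && !is.null(mask)) {
    if (length(mask) != ncol(H)) stop("dropout mask length mismatch", call. = FALSE)
    H <- sweep(H, 2L, mask / keep, `*`)
  }
  Z2 <- sweep(H %*% params$W2, 2L, params$b2, `+`)
  P <- sigmoid(Z2)
  list(P = P, cache = list(x = x, Z1 = Z1, H = H, P = P,
                           mask = if (mode == "train") mask else NULL,
                           keep = keep, params = params))
}

#' Mean binary cross-entropy over the two output units
#'
#' Predictions are clipped into `[eps, 1 - eps]` before the logarithm so the
#' loss is finite for saturated outputs.
#'
#' @param P n x 2 matrix (or length-2 vector) of predicted probabilities.
#' @param Y matching matrix/vector of binary targets.
#' @param eps clipping constant.
#' @return non-negative scalar.
#' @export
nn_loss <- function(P, Y, eps = 1e-12) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  stopifnot(all(dim(P) == dim(Y)))
  Pc <- pmin(pmax(P, eps), 1 - eps)
  -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc))
}

#' Backward pass: gradients of the mean cross-entropy loss
#'
#' Exact analytic gradients for every weight and bias; hidden units zeroed
#' by the dropout mask receive (and transmit) zero gradient.
#'
#' @param cache the `cache` element returned by [nn_forward()].
#' @param Y binary target matrix matching the forward batch.
#' @return list of gradients `W1`, `b1`, `W2`, `b2` with the shapes of
#'   `glyco_params`.
#' @export
nn_backward <- function(cache, Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  n <- nrow(cache$P)
  if (nrow(Y) != n || ncol(Y) != 2L)
    stop("label shape does not match forward cache", call. = FALSE)
  # d(mean BCE)/dZ2 for sigmoid outputs; mean over n samples x 2 units
  dZ2 <- (cache$P - Y) / (2 * n)
  dW2 <- crossprod(cache$H, dZ2)
  db2 <- colSums(dZ2)
  dH <- tcrossprod(dZ2, cache$params$W2)
  if (!is.null(cache$mask))
    dH <- sweep(dH, 2L, cache$mask / cache$keep, `*`)
  dZ1 <- dH * (cache$Z1 > 0)
  dW1 <- crossprod(cache$x, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Cyclical learning-rate schedule
#'
#' `rate = ilr * d^floor(epoch / c) * exp(-k * (epoch mod c))`: within a
#' cycle the rate decays exponentially at rate `k`; each new cycle restarts
#' at a peak reduced by the descent coefficient `d`. With the default
#' constants the schedule starts at 0.25 and cycle 2 restarts at 0.2375.
#'
#' @param epoch zero-based epoch index, `0 <= epoch < n_cycles * c`.
#' @param h a `glyco_hyperparams` object.
#' @return positive scalar learning rate (vectorised over `epoch`).
#' @export
nn_learning_rate <- function(epoch, h) {
  if (any(epoch < 0 | epoch >= h$n_cycles * h$c))
    stop("epoch out of range [0, ", h$n_cycles * h$c, ")", call. = FALSE)
  h$ilr * h$d^(epoch %/% h$c) * exp(-h$k * (epoch %% h$c))
}

#' Classification accuracy of paired sigmoid outputs
#'
#' A sample is called positive when the positive unit's probability strictly
#' exceeds the negative unit's; an exact tie resolves to negative (the
#' conservative choice for triage, fewer false positives). Accuracy is the
#' fraction of samples whose call matches the label's 1-position.
#'
#' @param P n x 2 matrix of predicted probabilities.
#' @param Y n x 2 binary label matrix.
#' @return fraction in [0, 1].
#' @export
nn_accuracy <- function(P, Y) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  stopifnot(nrow(P) > 0L, all(dim(P) == dim(Y)))
  pred_pos <- P[, 1L] > P[, 2L]
  mean(pred_pos == (Y[, 1L] == 1))
}

#' Train one triage classifier with early stopping
#'
#' Full-batch gradient descent for `n_cycles * c` epochs under the cyclical
#' learning-rate schedule, with one fresh dropout mask per epoch. Training
#' always runs the full schedule; early stopping selects the parameter
#' snapshot from the epoch with the highest test-set accuracy (the earliest
#' such epoch on ties), which is what the function returns.
#'
#' @param train_x,train_y training descriptor matrix and n x 2 label matrix.
#' @param test_x,test_y held-out test set used only to pick the snapshot.
#' @param h a `glyco_hyperparams`.
#' @return list with `params` (best snapshot, a `glyco_params`), `trace`
#'   (data.frame epoch/lr/loss/train_acc/test_acc) and `best_epoch`
#'   (zero-based).
#' @export
nn_train <- function(train_x, train_y, test_x, test_y, h = nn_hyperparams()) {
  stopifnot(nrow(train_x) == nrow(train_y), nrow(test_x) == nrow(test_y),
            ncol(train_x) == ncol(test_x), nrow(test_x) > 0L)
  if (!is.null(h$seed)) set.seed(h$seed)
  params <- nn_init_params(ncol(train_x), h$hidden_units, seed = NULL)
  keep <- keep_probability(h)
  n_epochs <- h$n_cycles * h$c
  trace <- data.frame(epoch = integer(n_epochs), lr = numeric(n_epochs),
                      loss = numeric(n_epochs),
                      train_acc = numeric(n_epochs),
                      test_acc = numeric(n_epochs))
  best_acc <- -Inf
  best_epoch <- NA_integer_
  best_params <- params
  for (epoch in seq_len(n_epochs) - 1L) {
    lr <- nn_learning_rate(epoch, h)
    mask <- if (keep < 1) stats::rbinom(h$hidden_units, 1L, keep) else NULL
    fwd <- nn_forward(train_x, params, mode = "train", mask = mask, keep = keep)
    loss <- nn_loss(fwd$P, train_y)
    if (!is.finite(loss))
      stop("non-finite training loss at epoch ", epoch,
           ": learning rate diverged", call. = FALSE)
    grads <- nn_backward(fwd$cache, train_y)
    params$W1 <- params$W1 - lr * grads$W1
    params$b1 <- params$b1 - lr * grads$b1
    params$W2 <- params$W2 - lr * grads$W2
    params$b2 <- params$b2 - lr * grads$b2
    train_acc <- nn_accuracy(nn_forward(train_x, params)$P, train_y)
    test_acc <- nn_accuracy(nn_forward(test_x, params)$P, test_y)
    trace[epoch + 1L, ] <- list(epoch, lr, loss, train_acc, test_acc)
    if (test_acc > best_acc) {
      best_acc <- test_acc
      best_epoch <- epoch
      best_params <- params
    }
  }
  list(params = best_params, trace = trace, best_epoch = best_epoch)
}
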