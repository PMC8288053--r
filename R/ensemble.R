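#' Train a bagged ensemble of triage classifiers
#'
#' Each ensemble member trains on its own half-size subset of the training
#' set (see [make_bagging_subsets()]) against the shared test set used for
#' early stopping. Members vote with equal weight at prediction time.
#'
#' @param train_x,train_y full training descriptor matrix and n x 2 labels.
#' @param test_x,test_y shared early-stopping test set.
#' @param h a `glyco_hyperparams`; each member gets its own derived seed.
#' @param n_models number of members (default 5).
#' @param seed master seed for subset draws and member initialisation.
#' @return an object of class `glyco_ensemble`: `members` (list of
#'   `glyco_params`), `traces`, `hyper`, `n_features`, `vocab_hash`.
#' @export
train_ensemble <- function(train_x, train_y, test_x, test_y,
                           h = nn_hyperparams(), n_models = 5L, seed = NULL) {
  stopifnot(n_models >= 1L, nrow(train_x) == nrow(train_y))
  subset_seed <- if (is.null(seed)) NULL else seed
  subsets <- make_bagging_subsets(seq_len(nrow(train_x)), n_models,
                                  seed = subset_seed)
  member_seeds <- derive_seeds(seed, n_models)
  members <- vector("list", n_models)
  traces <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    hm <- h
    hm$seed <- member_seeds[[m]]
    idx <- subsets[[m]]
    fit <- nn_train(train_x[idx, , drop = FALSE],
                    train_y[idx, , drop = FALSE],
                    test_x, test_y, hm)
    members[[m]] <- fit$params
    traces[[m]] <- fit$trace
  }
  structure(list(members = members, traces = traces, hyper = h,
                 n_features = ncol(train_x),
                 vocab_hash = attr(train_x, "vocab_hash")),
            class = "glyco_ensemble")
}

#' @export
print.glyco_ensemble <- function(x, ...) {
  cat(sprintf("<glyco_ensemble> %d member(s), %d feature(s), hash %s\n",
              length(x$members), x$n_features,
              substr(x$vocab_hash %||% "none", 1, 8)))
  invisible(x)
}

#' Aggregate ensemble votes with a binomial confidence interval
#'
#' Each member casts a binary vote: 1 when its positive output unit is at
#' least as large as its negative unit. Votes are averaged into `p_hat` and
#' the vote proportion receives a normal-approximation binomial interval
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n_models)`, truncated to [0, 1].
#' Averaging raw member probabilities instead of rounded votes is available
#' via `type = "prob"` (the interval is then descriptive only).
#'
#' @param object a `glyco_ensemble`.
#' @param x descriptor matrix (rows = documents) or a `glyco_descriptor`.
#' @param z confidence multiplier (default 1.96, a 95 percent interval).
#' @param type `"vote"` (default, Bernoulli votes) or `"prob"`.
#' @param ... unused.
#' @return data.frame with columns `doc_id`, `p_hat`, `ci_low`, `ci_high`,
#'   `width`; the member vote matrix is attached as attribute `votes`.
#' @export
predict.glyco_ensemble <- function(object, x, z = 1.96,
                                   type = c("vote", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(x, "glyco_descriptor")) {
    ids <- x$doc_id
    xh <- x$vocab_hash
    x <- matrix(x$bits, nrow = 1L)
  } else {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    xh <- attr(x, "vocab_hash")
  }
  if (!is.null(xh) && !is.null(object$vocab_hash) &&
      !identical(xh, object$vocab_hash))
    stop("vocabulary hash mismatch between descriptors and ensemble",
         call. = FALSE)
  if (ncol(x) != object$n_features)
    stop("feature dimension mismatch", call. = FALSE)
  n_models <- length(object$members)
  votes <- vapply(object$members, function(p) {
    P <- nn_forward(x, p)$P
    if (type == "vote") as.numeric(P[, 1L] >= P[, 2L]) else P[, 1L]
  }, numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  p_hat <- rowMeans(votes)
  half <- z * sqrt(p_hat * (1 - p_hat) / n_models)
  out <- data.frame(doc_id = ids, p_hat = p_hat,
                    ci_low = pmax(p_hat - half, 0),
                    ci_high = pmin(p_hat + half, 1))
  # the decision rule compares the distance between the *untruncated*
  # interval limits, 2 z sqrt(p(1-p)/n); truncation only tidies the bounds
  out$width <- 2 * half
  attr(out, "votes") <- votes
  out
}

#' Three-way triage decision from an aggregated prediction
#'
#' The call is positive when `p_hat` rounds to 1 (strictly above 0.5; an
#' exact 0.5 rounds to negative, the conservative triage choice) — unless
#' the confidence-interval width strictly exceeds `threshold`, in which case
#' the prediction is flagged ambiguous and routed to human review.
#'
#' When the true label is known the outcome follows the curation rule:
#' `correct` when the rounded aggregate matches the truth (whatever the
#' interval), otherwise `ambiguous` when the interval width exceeds
#' `threshold` (the reviewer can rescue it) and `wrong` when it does not.
#' Ambiguous outcomes are thus a subset of the incorrectly-rounded
#' predictions.
#'
#' @param agg data.frame from [predict.glyco_ensemble()].
#' @param truth optional vector of true labels (`"positive"`/`"negative"`).
#' @param threshold ambiguity threshold on interval width (default 0.5,
#'   strict comparison: a width of exactly 0.5 is decisive).
#' @return `agg` with added columns `call` and (when truth is given)
#'   `outcome`.
#' @export
decide <- function(agg, truth = NULL, threshold = 0.5) {
  stopifnot(is.data.frame(agg), all(c("p_hat", "width") %in% names(agg)))
  rounded <- ifelse(agg$p_hat > 0.5, "positive", "negative")
  agg$call <- ifelse(agg$width > threshold, "ambiguous", rounded)
  if (!is.null(truth)) {
    stopifnot(length(truth) == nrow(agg))
    agg$outcome <- ifelse(rounded == truth, "correct",
                          ifelse(agg$width > threshold, "ambiguous", "wrong"))
  }
  agg
}

#' Evaluate an ensemble on a labelled set
#'
#' Computes the triage metrics: `accuracy` (fraction of samples whose
#' aggregated decision is correct), `accuracy_with_ambiguous` (fraction
#' correct or flagged ambiguous — the paperless analogue of recovering
#' flagged samples through human review), `precision` and `recall` on the
#' positive class over decisive calls only, and the `ambiguous_fraction`.
#' When no decisive positive call exists precision is undefined and
#' reported as `NA`, never 0.
#'
#' @param ens a `glyco_ensemble`.
#' @param x descriptor matrix.
#' @param labels `"positive"`/`"negative"` vector parallel to rows of `x`.
#' @param z,threshold passed to [predict.glyco_ensemble()] and [decide()].
#' @return named list of metrics, all in [0, 1] (or NA where undefined).
#' @export
evaluate_ensemble <- function(ens, x, labels, z = 1.96, threshold = 0.5) {
  stopifnot(nrow(x) == length(labels), nrow(x) > 0L)
  dec <- decide(predict(ens, x, z = z), truth = labels, threshold = threshold)
  correct <- dec$outcome == "correct"
  ambiguous <- dec$outcome == "ambiguous"
  decisive <- !ambiguous
  tp <- sum(decisive & dec$call == "positive" & labels == "positive")
  fp <- sum(decisive & dec$call == "positive" & labels == "negative")
  fn <- sum(decisive & dec$call == "negative" & labels == "positive")
  list(
    accuracy = mean(correct),
    accuracy_with_ambiguous = mean(correct | ambiguous),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ambiguous_fraction = mean(ambiguous)
  )
}

#' Save/load an ensemble as a portable JSON container
#'
#' Stores hyperparameters, the vocabulary hash and flattened weight arrays;
#' no binary serialisation, so models survive across R versions and can be
#' inspected with any JSON tool.
#'
#' @param ens a `glyco_ensemble`.
#' @param path file path.
#' @export
write_ensemble <- function(ens, path) {
  payload <- list(
    format = "glycotriage-ensemble-v1",
    hyper = unclass(ens$hyper),
    n_features = ens$n_features,
    vocab_hash = ens$vocab_hash,
    members = lapply(ens$members, function(p) list(
      W1 = as.numeric(p$W1), b1 = p$b1, W2 = as.numeric(p$W2), b2 = p$b2,
      dim = c(nrow(p$W1), ncol(p$W1))))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(pl$format, "glycotriage-ensemble-v1"))
    stop("not a glycotriage ensemble file", call. = FALSE)
  hy <- lapply(pl$hyper, function(v) if (is.list(v)) unlist(v) else v)
  h <- do.call(nn_hyperparams, hy)
  members <- lapply(pl$members, function(m) {
    dm <- as.integer(unlist(m$dim))
    structure(list(
      W1 = matrix(as.numeric(unlist(m$W1)), dm[1], dm[2]),
      b1 = as.numeric(unlist(m$b1)),
      W2 = matrix(as.numeric(unlist(m$W2)), dm[2], 2L),
      b2 = as.numeric(unlist(m$b2))), class = "glyco_params")
  })
  structure(list(members = members, traces = NULL, hyper = h,
                 n_features = as.integer(pl$n_features),
                 vocab_hash = pl$vocab_hash),
            class = "glyco_ensemble")
}
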