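#' Encode a curation label as a binary pair
#'
#' Positive publications (experimental O-GlcNAcylation demonstrated) map to
#' `(1, 0)`, negative to `(0, 1)`: the first unit is the probability of
#' containing experimental evidence, the second of not containing it.
#'
#' @param label `"positive"` or `"negative"` (anything else is rejected).
#' @return integer vector of length 2.
#' @export
encode_label <- function(label) {
  switch(label,
         positive = c(1L, 0L),
         negative = c(0L, 1L),
         stop("unknown label: ", label, call. = FALSE))
}

#' @rdname encode_label
#' @param labels character vector of labels.
#' @return `encode_labels()`: an n x 2 integer matrix, one row per label.
#' @export
encode_labels <- function(labels) {
  t(vapply(labels, encode_label, integer(2L), USE.NAMES = FALSE))
}

labeled_set <- function(ids, labels) {
  stopifnot(length(ids) == length(labels))
  data.frame(doc_id = ids, label = labels, stringsAsFactors = FALSE)
}

balance_ok <- function(labels, tol) {
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  abs(n_pos - n_neg) / length(labels) < tol
}

#' Shuffle-and-slice train/test/validation splits with a balance acceptance test
#'
#' The pool is shuffled and sliced into train/test/validation parts of the
#' requested fractions (test and validation sizes are floored; training gets
#' the remainder, so a balanced pool of 1340 yields 670/335/335). A candidate
#' split is accepted only when, within every set, the positive/negative
#' imbalance `|n_pos - n_neg| / n` is strictly below `balance_tol`;
#' otherwise the pool is reshuffled, up to `max_retries` times. The
#' acceptance test approximates a binomial label distribution in each set.
#'
#' @param ids document identifiers.
#' @param labels parallel vector of `"positive"`/`"negative"`.
#' @param fractions train/test/validation fractions summing to 1.
#' @param balance_tol strict per-set imbalance bound (default 0.01, i.e.
#'   "less than a 1 percent difference").
#' @param max_retries reshuffles before giving up.
#' @param seed optional integer; with a seed the split is bit-reproducible.
#'   Seedless mode reproduces the unseeded shuffling protocol.
#' @return named list of data.frames (`train`, `test`, `validation`), each
#'   with columns `doc_id` and `label`; the seed and the number of shuffles
#'   used are attached as attributes.
#' @export
make_splits <- function(ids, labels, fractions = c(0.5, 0.25, 0.25),
                        balance_tol = 0.01, max_retries = 1000L, seed = NULL) {
  n <- length(ids)
  stopifnot(n == length(labels), n >= 8L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  assert_scalar_number(balance_tol, "balance_tol", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (sum(labels == "positive") != sum(labels == "negative"))
    warning("pool is not class-balanced; balance acceptance may be slow or fail")
  n_test <- floor(n * fractions[2])
  n_val <- floor(n * fractions[3])
  n_train <- n - n_test - n_val
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    perm <- sample.int(n)
    i_train <- perm[seq_len(n_train)]
    i_test <- perm[n_train + seq_len(n_test)]
    i_val <- perm[n_train + n_test + seq_len(n_val)]
    if (balance_ok(labels[i_train], balance_tol) &&
        balance_ok(labels[i_test], balance_tol) &&
        balance_ok(labels[i_val], balance_tol)) {
      out <- list(train = labeled_set(ids[i_train], labels[i_train]),
                  test = labeled_set(ids[i_test], labels[i_test]),
                  validation = labeled_set(ids[i_val], labels[i_val]))
      attr(out, "seed") <- seed
      attr(out, "shuffles") <- try
      attr(out, "balance_tol") <- balance_tol
      return(out)
    }
  }
  stop("no balanced split found in ", max_retries,
       " shuffles; balance request may be unsatisfiable", call. = FALSE)
}

#' Half-set bagging subsets of the training set
#'
#' Each of the `n_models` ensemble members trains on its own subset obtained
#' by shuffling the training ids and keeping half of them: a draw without
#' replacement within a subset, independent across subsets (not a classical
#' with-replacement bootstrap).
#'
#' @param train_ids vector of training document ids (or indices).
#' @param n_models number of subsets (default 5).
#' @param seed optional integer for reproducibility.
#' @return list of `n_models` vectors, each of length `floor(n/2)`.
#' @export
make_bagging_subsets <- function(train_ids, n_models = 5L, seed = NULL) {
  stopifnot(length(train_ids) >= 2L, n_models >= 1L)
  if (!is.null(seed)) set.seed(seed)
  half <- floor(length(train_ids) / 2L)
  lapply(seq_len(n_models), function(m) sample(train_ids, half))
}

#' Write a split manifest
#'
#' CSV with columns `doc_id`, `set`, `label`; the header comment records the
#' seed and balance tolerance for provenance.
#'
#' @param splits result of [make_splits()].
#' @param path output CSV path.
#' @export
write_split_manifest <- function(splits, path) {
  rows <- do.call(rbind, lapply(names(splits), function(s)
    cbind(splits[[s]][, "doc_id", drop = FALSE], set = s,
          label = splits[[s]]$label)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# glycotriage splits seed=%s balance_tol=%s",
                     attr(splits, "seed") %||% "none",
                     attr(splits, "balance_tol") %||% NA), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}
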