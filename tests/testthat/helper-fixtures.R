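# Shared fixtures and independent oracles used across test files.

# minimal lexicon set with known, disjoint vocabularies
make_test_lexicons <- function() {
  lexicons(
    word_lists = list(
      methods = c("immunoblotting", "mass spectrometry"),
      biology = c("protein", "expression")
    ),
    regex_lists = list(
      oglcnac = "\\boglcnac\\w*",
      stsites = "\\b(?:ser|thr)\\d{1,4}\\b",
      phospho = "\\bphospho\\w*"
    ),
    protein_names = c("tau", "p53", "histone h3"),
    organism_names = c("human", "mouse"),
    stop_words = c("all rights reserved")
  )
}

# build a glyco_tagged document directly from a list of tag vectors
make_tagged <- function(doc_id, tag_sentences) {
  structure(list(
    doc_id = doc_id,
    sentences = lapply(tag_sentences, function(tags)
      list(tags = tags, source_text = paste(tags, collapse = " ")))),
    class = "glyco_tagged")
}

# independent corpus-level expression counter (plain accumulation loop,
# no table(), no vectorised shortcut shared with the implementation)
brute_count_expressions <- function(tagged_docs) {
  env <- new.env(parent = emptyenv())
  for (d in tagged_docs) {
    for (s in d$sentences) {
      key <- paste(s$tags, collapse = " ")
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  out <- vapply(ls(env), function(k) env[[k]], integer(1))
  out
}

# independent brute-force digestion: enumerate every substring bounded by
# cleavage points and count internal cleavage sites directly
brute_digest <- function(sequence, max_missed = 0L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_cut <- vapply(seq_len(n - 1), function(i)
    chars[i] %in% c("K", "R") && chars[i + 1] != "P", logical(1))
  cuts <- c(0L, which(is_cut), n)
  res <- list()
  for (a in seq_along(cuts)) {
    for (b in seq_along(cuts)) {
      if (b <= a) next
      internal <- sum(cuts > cuts[a] & cuts < cuts[b])
      if (internal <= max_missed)
        res[[length(res) + 1L]] <- c(start = cuts[a] + 1L, end = cuts[b],
                                     missed = internal)
    }
  }
  df <- as.data.frame(do.call(rbind, res))
  df[order(df$start, df$end), ]
}

random_aa_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

# flatten/unflatten network parameters for finite-difference checking
flatten_params <- function(p) c(as.numeric(p$W1), p$b1, as.numeric(p$W2), p$b2)
unflatten_params <- function(v, n_features, hidden) {
  i <- 0L
  take <- function(k) { out <- v[i + seq_len(k)]; i <<- i + k; out }
  structure(list(
    W1 = matrix(take(n_features * hidden), n_features, hidden),
    b1 = take(hidden),
    W2 = matrix(take(hidden * 2L), hidden, 2L),
    b2 = take(2L)), class = "glyco_params")
}

# central finite-difference gradient of the training loss
numeric_gradient <- function(x, y, params, mask = NULL, keep = 1,
                             step = 1e-5) {
  n_features <- nrow(params$W1)
  hidden <- ncol(params$W1)
  v <- flatten_params(params)
  mode <- if (is.null(mask)) "eval" else "train"
  vapply(seq_along(v), function(j) {
    vp <- v; vp[j] <- vp[j] + step
    vm <- v; vm[j] <- vm[j] - step
    lp <- nn_loss(nn_forward(x, unflatten_params(vp, n_features, hidden),
                             mode = mode, mask = mask, keep = keep)$P, y)
    lm <- nn_loss(nn_forward(x, unflatten_params(vm, n_features, hidden),
                             mode = mode, mask = mask, keep = keep)$P, y)
    (lp - lm) / (2 * step)
  }, numeric(1))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-8)

# random 0/1 feature matrix with no all-zero row: a zero row with zero
# biases sits exactly on the ReLU kink, where finite differences are
# ill-defined (a measure-zero configuration for real descriptors)
random_binary_features <- function(n, d) {
  x <- matrix(rbinom(n * d, 1, 0.5), n, d)
  zero <- rowSums(x) == 0
  x[cbind(which(zero), sample(d, sum(zero), replace = TRUE))] <- 1L
  x
}
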