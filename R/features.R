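render_expression <- function(sentence) paste(sentence$tags, collapse = " ")

#' Build the tag-pattern vocabulary from training documents
#'
#' Every retained tag sentence, rendered as its space-joined tag chain, is an
#' "expression". The vocabulary keeps the expressions whose total number of
#' occurrences across the whole training corpus (documents concatenated, so
#' counts pool across files) reaches `min_count`. Expressions are ordered
#' lexicographically (C locale) so vector indices are reproducible across
#' runs and machines.
#'
#' The vocabulary must be built from training documents only; supplying
#' held-out documents here leaks test information into the feature space.
#'
#' @param training_docs list of `glyco_tagged` documents.
#' @param min_count minimum corpus-level occurrence count (default 4).
#' @return an object of class `glyco_vocab` with fields `expressions`,
#'   `min_count`, `source_doc_ids` and a content `hash`.
#' @export
build_vocabulary <- function(training_docs, min_count = 4L) {
  assert_scalar_number(min_count, "min_count", lower = 1)
  all_expr <- unlist(lapply(training_docs, function(d)
    vapply(d$sentences, render_expression, character(1))), use.names = FALSE)
  if (is.null(all_expr)) all_expr <- character()
  counts <- table(all_expr)
  expressions <- as.character(names(counts)[counts >= min_count])
  expressions <- sort(expressions, method = "radix")
  obj <- list(
    expressions = expressions,
    min_count = as.integer(min_count),
    source_doc_ids = vapply(training_docs, `[[`, character(1), "doc_id")
  )
  obj$hash <- digest::digest(list(obj$expressions, obj$min_count))
  class(obj) <- "glyco_vocab"
  obj
}

#' @export
print.glyco_vocab <- function(x, ...) {
  cat(sprintf("<glyco_vocab> %d expression(s), min_count = %d, hash %s\n",
              length(x$expressions), x$min_count, substr(x$hash, 1, 8)))
  invisible(x)
}

#' Binary descriptor vector of a document over a vocabulary
#'
#' Bit i is 1 when expression i occurs at least once in the document (a tag
#' sentence whose rendered tag chain equals the expression exactly);
#' repetition does not change the bit. This strict presence/absence encoding
#' is deliberate: no counts, no weighting.
#'
#' @param doc a `glyco_tagged` document.
#' @param vocab a `glyco_vocab`.
#' @return an object of class `glyco_descriptor`: fields `doc_id` and `bits`
#'   (integer 0/1 vector aligned with `vocab$expressions`).
#' @export
vectorize <- function(doc, vocab) {
  stopifnot(inherits(vocab, "glyco_vocab"))
  present <- unique(vapply(doc$sentences, render_expression, character(1)))
  bits <- as.integer(vocab$expressions %in% present)
  structure(list(doc_id = doc$doc_id, bits = bits, vocab_hash = vocab$hash),
            class = "glyco_descriptor")
}

#' Descriptor matrix of a corpus
#'
#' @param docs list of `glyco_tagged`.
#' @param vocab a `glyco_vocab`.
#' @return integer 0/1 matrix, one row per document (rownames = doc ids),
#'   one column per vocabulary expression, with the vocabulary hash attached
#'   as attribute `vocab_hash`.
#' @export
vectorize_corpus <- function(docs, vocab) {
  bits <- vapply(docs, function(d) vectorize(d, vocab)$bits,
                 integer(length(vocab$expressions)))
  x <- if (length(vocab$expressions) == 1L) matrix(bits, ncol = 1L) else t(bits)
  if (length(vocab$expressions) == 0L)
    x <- matrix(integer(), nrow = length(docs), ncol = 0L)
  rownames(x) <- vapply(docs, `[[`, character(1), "doc_id")
  colnames(x) <- vocab$expressions
  attr(x, "vocab_hash") <- vocab$hash
  x
}

#' Write/read a vocabulary as plain text
#'
#' One expression per line; a comment header records `min_count` and the
#' content hash so models and descriptor matrices can be checked against the
#' vocabulary that produced them.
#'
#' @param vocab a `glyco_vocab`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  hdr <- c(sprintf("# glycotriage vocabulary v1 min_count=%d hash=%s",
                   vocab$min_count, vocab$hash))
  writeLines(c(hdr, vocab$expressions), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- readLines(path, warn = FALSE)
  hdr <- x[1]
  mc <- as.integer(sub(".*min_count=(\\d+).*", "\\1", hdr))
  expressions <- x[-1]
  obj <- list(expressions = expressions, min_count = mc,
              source_doc_ids = character())
  obj$hash <- digest::digest(list(obj$expressions, obj$min_count))
  class(obj) <- "glyco_vocab"
  stored <- sub(".*hash=([0-9a-f]+).*", "\\1", hdr)
  if (!identical(stored, obj$hash))
    warning("vocabulary hash mismatch: file edited since it was written")
  obj
}
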