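tag_alphabet <- function() {
  c("PROTEIN", "ORGANISM", "OGLCNAC", "PHOSPHO", "STSITES", "AMINOACIDS",
    "PEPTIDES", "NUCLEICACIDS", "PRONOMINIAL", "CONCLUSION", "DESCRIPTION",
    "BIOLOGY", "GLYCOBIOLOGY", "CELLS", "METHODS")
}

# one surface term per tag, drawn from the shipped default lexicons, so a
# surface-realised corpus round-trips through clean_text/tag_document
surface_terms <- function() {
  c(PROTEIN = "tau", ORGANISM = "human", OGLCNAC = "oglcnacylation",
    PHOSPHO = "phosphorylation", STSITES = "ser400", AMINOACIDS = "serine",
    PEPTIDES = "peptides", NUCLEICACIDS = "mrna", PRONOMINIAL = "we",
    CONCLUSION = "demonstrated", DESCRIPTION = "detected",
    BIOLOGY = "protein", GLYCOBIOLOGY = "glycosylation", CELLS = "hela",
    METHODS = "immunoblotting")
}

#' Specification of a synthetic labelled corpus
#'
#' The generator emulates a triage corpus at the tag-sentence level: a fixed
#' set of discriminative "signal" patterns appears in positive documents
#' with probability `p_signal_pos` and in negative documents with
#' probability `p_signal_neg`, on top of label-independent background
#' patterns and single-tag filler sentences (which the >1-tag retention rule
#' discards). Signal strength is therefore fully controllable, and the
#' optimal achievable accuracy has a closed form by enumeration
#' ([bayes_accuracy()]).
#'
#' Defaults give a desk-scale analogue of a curation corpus: 200 documents,
#' balanced classes, 5 signal patterns at 0.9/0.1 inclusion probabilities.
#'
#' @param n_docs number of documents (>= 2).
#' @param positive_fraction fraction of positive documents.
#' @param n_signal_patterns,n_background_patterns pattern counts.
#' @param p_signal_pos,p_signal_neg per-pattern inclusion probability in
#'   positive/negative documents (`p_signal_pos >= p_signal_neg` for a
#'   learnable signal).
#' @param p_background inclusion probability of each background pattern in
#'   any document.
#' @param sentences_per_doc integer range: total sentences per document
#'   (padded with single-tag fillers).
#' @param seed integer seed; a fixed seed makes generation byte-identical.
#' @param surface if `TRUE`, documents are realised as lower-case text whose
#'   words are default-lexicon terms separated by untagged filler words, so
#'   the full cleaning/tagging path is exercised; otherwise documents carry
#'   tag sentences directly.
#' @return an object of class `glyco_corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 200L, positive_fraction = 0.5,
                        n_signal_patterns = 5L, n_background_patterns = 20L,
                        p_signal_pos = 0.9, p_signal_neg = 0.1,
                        p_background = 0.5, sentences_per_doc = c(8L, 20L),
                        seed = NULL, surface = FALSE) {
  assert_scalar_number(n_docs, "n_docs", lower = 2)
  assert_scalar_number(positive_fraction, "positive_fraction", 0, 1)
  for (p in c("p_signal_pos", "p_signal_neg", "p_background"))
    assert_scalar_number(get(p), p, 0, 1)
  if (p_signal_pos < p_signal_neg)
    stop("p_signal_pos must be >= p_signal_neg for a learnable signal",
         call. = FALSE)
  stopifnot(length(sentences_per_doc) == 2L,
            sentences_per_doc[1] <= sentences_per_doc[2])
  structure(list(n_docs = as.integer(n_docs),
                 positive_fraction = positive_fraction,
                 n_signal_patterns = as.integer(n_signal_patterns),
                 n_background_patterns = as.integer(n_background_patterns),
                 p_signal_pos = p_signal_pos, p_signal_neg = p_signal_neg,
                 p_background = p_background,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 seed = seed, surface = isTRUE(surface)),
            class = "glyco_corpus_spec")
}

draw_patterns <- function(n, alphabet, existing = character()) {
  out <- character()
  while (length(out) < n) {
    len <- sample(2:4, 1L)
    pat <- paste(sample(alphabet, len, replace = TRUE), collapse = " ")
    if (!pat %in% c(out, existing)) out <- c(out, pat)
  }
  out
}

realize_sentence <- function(pattern_tags, fillers, terms) {
  words <- terms[pattern_tags]
  glue <- sample(fillers, length(words), replace = TRUE)
  paste(paste(glue, words), collapse = " ")
}

#' Generate a synthetic labelled corpus
#'
#' @param spec a [corpus_spec()].
#' @return list with `docs` (list of `glyco_raw_doc` with labels), `labels`
#'   (named character vector), `truth` (data.frame of planted patterns with
#'   their role and inclusion probabilities) and `plants` (per-document list
#'   of the patterns actually planted, for round-trip checking).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "glyco_corpus_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  alphabet <- tag_alphabet()
  signal <- draw_patterns(spec$n_signal_patterns, alphabet)
  background <- draw_patterns(spec$n_background_patterns, alphabet, signal)
  n_pos <- round(spec$n_docs * spec$positive_fraction)
  labels <- sample(c(rep("positive", n_pos),
                     rep("negative", spec$n_docs - n_pos)))
  fillers <- c("the", "of", "was", "at", "with", "a", "in", "by", "for")
  terms <- surface_terms()
  docs <- vector("list", spec$n_docs)
  plants <- vector("list", spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    p_sig <- if (labels[i] == "positive") spec$p_signal_pos else spec$p_signal_neg
    keep_sig <- stats::runif(length(signal)) < p_sig
    keep_bg <- stats::runif(length(background)) < spec$p_background
    sentences <- c(signal[keep_sig], background[keep_bg])
    plants[[i]] <- sentences
    n_target <- sample(spec$sentences_per_doc[1]:spec$sentences_per_doc[2], 1L)
    n_fill <- max(0L, n_target - length(sentences))
    fill <- if (n_fill > 0L)
      vapply(seq_len(n_fill), function(j) sample(alphabet, 1L), character(1))
    else character()
    sentences <- sample(c(sentences, fill))
    doc_id <- sprintf("doc%04d", i)
    if (spec$surface) {
      text <- paste(vapply(strsplit(sentences, " ", fixed = TRUE),
                           realize_sentence, character(1),
                           fillers = fillers, terms = terms),
                    collapse = ". ")
    } else {
      text <- paste(sentences, collapse = ". ")
    }
    docs[[i]] <- raw_document(doc_id, paste0(text, "."), labels[i])
  }
  names(labels) <- vapply(docs, `[[`, character(1), "doc_id")
  names(plants) <- names(labels)
  truth <- data.frame(
    pattern = c(signal, background),
    role = rep(c("signal", "background"),
               c(length(signal), length(background))),
    p_pos = c(rep(spec$p_signal_pos, length(signal)),
              rep(spec$p_background, length(background))),
    p_neg = c(rep(spec$p_signal_neg, length(signal)),
              rep(spec$p_background, length(background))),
    stringsAsFactors = FALSE)
  list(docs = docs, labels = labels, truth = truth, plants = plants)
}

#' Parse a tag-level document into tag sentences
#'
#' Synthetic documents generated with `surface = FALSE` already consist of
#' period-separated tag chains; this parser splits them directly, applying
#' the same >1-tag retention rule as [tag_document()], without any lexicon.
#'
#' @param doc a `glyco_raw_doc` whose text is period-separated tag chains.
#' @return a `glyco_tagged` document.
#' @export
parse_tag_document <- function(doc) {
  stopifnot(inherits(doc, "glyco_raw_doc"))
  segments <- trimws(strsplit(doc$text, ".", fixed = TRUE)[[1]])
  segments <- segments[nzchar(segments)]
  sentences <- list()
  for (seg in segments) {
    tags <- strsplit(seg, "[[:space:]]+")[[1]]
    tags <- tags[nzchar(tags)]
    if (length(tags) > 1L)
      sentences[[length(sentences) + 1L]] <- list(tags = tags,
                                                  source_text = seg)
  }
  structure(list(doc_id = doc$doc_id, sentences = sentences),
            class = "glyco_tagged")
}

#' Write a synthetic corpus in the pipeline's on-disk layout
#'
#' One `.txt` file per document, a `labels.csv` manifest and a `truth.csv`
#' table of planted patterns — the same layout [read_corpus()] consumes.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in corpus$docs)
    writeLines(d$text, file.path(dir, paste0(d$doc_id, ".txt")))
  utils::write.csv(data.frame(doc_id = names(corpus$labels),
                              label = unname(corpus$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(corpus$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Exact Bayes-optimal accuracy of a synthetic corpus specification
#'
#' Background patterns and fillers are label-independent, so the optimal
#' classifier observes only the presence/absence configuration of the
#' signal patterns. This function enumerates all 2^s configurations,
#' assigns each to the a-posteriori most probable class and sums the
#' resulting probability mass — a brute-force oracle no trained model can
#' beat except by sampling noise.
#'
#' @param spec a [corpus_spec()] with at most 12 signal patterns (the
#'   enumeration is refused above that).
#' @return expected accuracy of the optimal classifier, in [0, 1].
#' @export
bayes_accuracy <- function(spec) {
  stopifnot(inherits(spec, "glyco_corpus_spec"))
  s <- spec$n_signal_patterns
  if (s > 12L)
    stop("enumeration over 2^", s, " configurations refused (> 12 patterns)",
         call. = FALSE)
  pi_pos <- spec$positive_fraction
  if (s == 0L) return(max(pi_pos, 1 - pi_pos))
  acc <- 0
  for (cfg in 0:(2^s - 1L)) {
    x <- as.integer(intToBits(cfg))[seq_len(s)]
    p_cfg_pos <- prod(ifelse(x == 1L, spec$p_signal_pos, 1 - spec$p_signal_pos))
    p_cfg_neg <- prod(ifelse(x == 1L, spec$p_signal_neg, 1 - spec$p_signal_neg))
    acc <- acc + max(pi_pos * p_cfg_pos, (1 - pi_pos) * p_cfg_neg)
  }
  acc
}
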