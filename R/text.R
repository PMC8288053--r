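#' Construct a raw publication document
#'
#' @param doc_id non-empty identifier (typically a PMID rendered as text).
#' @param text document text (may be empty).
#' @param label one of `"positive"`, `"negative"`, `"unknown"`.
#' @return an object of class `glyco_raw_doc`.
#' @export
raw_document <- function(doc_id, text = "", label = "unknown") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  label <- match.arg(label, c("positive", "negative", "unknown"))
  structure(list(doc_id = doc_id, text = as.character(text), label = label),
            class = "glyco_raw_doc")
}

#' Read a corpus of plain-text documents
#'
#' One UTF-8 text file per document; the filename stem is the document id.
#' Labels, when available, come from a two-column CSV (`doc_id,label`).
#'
#' @param dir directory of `.txt` files.
#' @param labels_csv optional path to a `doc_id,label` CSV.
#' @return list of `glyco_raw_doc`.
#' @export
read_corpus <- function(dir, labels_csv = NULL) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no .txt documents found in ", dir, call. = FALSE)
  lab <- NULL
  if (!is.null(labels_csv)) {
    lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
    stopifnot(all(c("doc_id", "label") %in% names(lab)))
  }
  lapply(files, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    lb <- "unknown"
    if (!is.null(lab) && id %in% lab$doc_id)
      lb <- lab$label[match(id, lab$doc_id)]
    raw_document(id, paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                           collapse = "\n"), lb)
  })
}

#' Clean publication text for tagging
#'
#' Applies the three removal rules used to normalise converted publication
#' text: (i) every span enclosed in brackets, parentheses or braces is
#' deleted, iterating so nested spans vanish too; (ii) every character that
#' is not alphanumeric, whitespace or a period is deleted outright, merging
#' its neighbours (so `"O-GlcNAc"` becomes `"OGlcNAc"`); (iii) stop phrases
#' are removed case-insensitively, after themselves being passed through
#' rules (i)-(ii). Whitespace is normalised to single spaces. The function
#' is total and idempotent: cleaning a cleaned string changes nothing.
#'
#' @param text character scalar (empty allowed).
#' @param stop_words character vector of stop phrases, or a
#'   `glyco_lexicons` object whose `stop_words` are used.
#' @return the cleaned string, containing only `A-Z a-z 0-9`, space and
#'   period.
#' @export
clean_text <- function(text, stop_words = character()) {
  if (inherits(stop_words, "glyco_lexicons")) stop_words <- stop_words$stop_words
  stopifnot(length(text) <= 1L)
  if (length(text) == 0L || is.na(text)) return("")
  x <- gsub("[[:space:]]+", " ", text)
  # iterate so nested bracketed spans are fully removed
  repeat {
    y <- gsub("\\([^()]*\\)|\\[[^][]*\\]|\\{[^{}]*\\}", " ", x, perl = TRUE)
    if (identical(y, x)) break
    x <- y
  }
  x <- gsub("[^A-Za-z0-9 .]", "", x)
  if (length(stop_words)) {
    stops <- vapply(stop_words, function(s) {
      s <- gsub("[[:space:]]+", " ", s)
      s <- gsub("\\([^()]*\\)|\\[[^][]*\\]|\\{[^{}]*\\}", " ", s, perl = TRUE)
      trimws(gsub(" +", " ", gsub("[^A-Za-z0-9 .]", "", s)))
    }, character(1))
    stops <- unique(stops[nzchar(stops)])
    if (length(stops)) {
      pat <- paste0("\\b(?:", paste(escape_regex(stops), collapse = "|"), ")\\b")
      repeat {
        y <- gsub(pat, " ", x, perl = TRUE, ignore.case = TRUE)
        if (identical(y, x)) break
        x <- y
      }
    }
  }
  trimws(gsub(" +", " ", x))
}

#' Keep the results/discussion portion of a document
#'
#' Scans for section headers with a dictionary of regular expressions and
#' returns only the spans opened by a "keep" header (Results, Discussion and
#' variants) and closed by the next recognised header of any kind. Because
#' layout-based PDF conversion often destroys headers, the full text is
#' returned unchanged when no keep header is found.
#'
#' @param text character scalar.
#' @param section_patterns a list with elements `keep` and `boundary`, each a
#'   named list/vector of regular expressions, matched case-sensitively so
#'   prose mentions ("these results show") are not mistaken for headers;
#'   defaults to the shipped `sections.yaml` dictionary.
#' @return character scalar.
#' @export
select_sections <- function(text, section_patterns = default_section_patterns()) {
  stopifnot(is.list(section_patterns), length(section_patterns$keep) > 0)
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return("")
  hits <- list()
  for (role in c("keep", "boundary")) {
    for (pat in unlist(section_patterns[[role]], use.names = FALSE)) {
      m <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (m[1] != -1L)
        hits[[length(hits) + 1L]] <- data.frame(
          start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L,
          keep = role == "keep")
    }
  }
  if (!length(hits)) return(text)
  hd <- do.call(rbind, hits)
  hd <- hd[order(hd$start, -hd$end), , drop = FALSE]
  # drop header matches overlapping an earlier (longer) header match
  keep_row <- logical(nrow(hd))
  last_end <- 0L
  for (i in seq_len(nrow(hd))) {
    if (hd$start[i] > last_end) {
      keep_row[i] <- TRUE
      last_end <- hd$end[i]
    }
  }
  hd <- hd[keep_row, , drop = FALSE]
  if (!any(hd$keep)) return(text)
  spans <- character()
  for (i in which(hd$keep)) {
    from <- hd$end[i] + 1L
    to <- if (i < nrow(hd)) hd$start[i + 1L] - 1L else nchar(text)
    if (from <= to) spans <- c(spans, substr(text, from, to))
  }
  trimws(gsub(" +", " ", paste(spans, collapse = " ")))
}

# one compiled matcher per dictionary, in priority order
lexicon_matchers <- function(lex) {
  literal_pattern <- function(terms) {
    if (!length(terms)) return(NULL)
    terms <- terms[order(-nchar(terms))]
    paste0("\\b(?:", paste(escape_regex(terms), collapse = "|"), ")\\b")
  }
  m <- list()
  for (cat in names(lex$regex_lists))
    m[[length(m) + 1L]] <- list(tag = toupper(cat), priority = 1L,
                                patterns = lex$regex_lists[[cat]])
  p <- literal_pattern(lex$protein_names)
  if (!is.null(p)) m[[length(m) + 1L]] <- list(tag = "PROTEIN", priority = 2L,
                                               patterns = p)
  p <- literal_pattern(lex$organism_names)
  if (!is.null(p)) m[[length(m) + 1L]] <- list(tag = "ORGANISM", priority = 3L,
                                               patterns = p)
  for (cat in names(lex$word_lists)) {
    p <- literal_pattern(lex$word_lists[[cat]])
    if (!is.null(p)) m[[length(m) + 1L]] <- list(tag = toupper(cat),
                                                 priority = 4L, patterns = p)
  }
  m
}

tag_segment <- function(segment, matchers) {
  cand <- list()
  for (mt in matchers) {
    for (pat in mt$patterns) {
      g <- gregexpr(pat, segment, perl = TRUE, ignore.case = TRUE)[[1]]
      if (g[1] == -1L) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = as.integer(g),
        len = attr(g, "match.length"),
        priority = mt$priority, tag = mt$tag)
    }
  }
  if (!length(cand)) return(character())
  cd <- do.call(rbind, cand)
  # left-to-right scan; at equal start the longest match wins, ties between
  # dictionaries broken by fixed priority (regex > protein > organism > word)
  cd <- cd[order(cd$start, -cd$len, cd$priority), , drop = FALSE]
  tags <- character()
  last_end <- 0L
  for (i in seq_len(nrow(cd))) {
    if (cd$start[i] > last_end) {
      tags <- c(tags, cd$tag[i])
      last_end <- cd$start[i] + cd$len[i] - 1L
    }
  }
  tags
}

#' Reduce a cleaned document to tag sentences
#'
#' Splits cleaned, section-selected text at periods and replaces every
#' dictionary match by its uppercase category tag (`PROTEIN`, `OGLCNAC`,
#' `STSITES`, ...). Untagged material is dropped. Only segments carrying
#' more than one tag are retained; the result is the document's "tag
#' sentence" representation used for vocabulary building.
#'
#' Matching is case-insensitive, left-to-right, longest-match-wins, with
#' dictionary priority regex lists > protein names > organism names > word
#' lists. The operation is a pure function of the text and lexicons.
#'
#' @param doc a `glyco_raw_doc` (its text must already be cleaned; see
#'   [process_document()] for the full path from raw text).
#' @param lexicons a `glyco_lexicons` object.
#' @return an object of class `glyco_tagged` with fields `doc_id` and
#'   `sentences`, each sentence a list with `tags` and `source_text`.
#' @export
tag_document <- function(doc, lexicons) {
  stopifnot(inherits(doc, "glyco_raw_doc"), inherits(lexicons, "glyco_lexicons"))
  matchers <- lexicon_matchers(lexicons)
  segments <- trimws(strsplit(doc$text, ".", fixed = TRUE)[[1]])
  segments <- segments[nzchar(segments)]
  sentences <- list()
  for (seg in segments) {
    tags <- tag_segment(seg, matchers)
    if (length(tags) > 1L)
      sentences[[length(sentences) + 1L]] <- list(tags = tags, source_text = seg)
  }
  structure(list(doc_id = doc$doc_id, sentences = sentences),
            class = "glyco_tagged")
}

#' @export
print.glyco_tagged <- function(x, ...) {
  cat(sprintf("<glyco_tagged> %s: %d tag sentence(s)\n",
              x$doc_id, length(x$sentences)))
  for (s in utils::head(x$sentences, 5L))
    cat("  [", paste(s$tags, collapse = " "), "]\n")
  if (length(x$sentences) > 5L) cat("  ...\n")
  invisible(x)
}

#' Full text-processing path for one document
#'
#' Cleaning, stop-phrase removal, section selection and tagging in the order
#' the triage pipeline applies them.
#'
#' @inheritParams tag_document
#' @param section_patterns see [select_sections()]; `NULL` skips section
#'   selection.
#' @return a `glyco_tagged` document.
#' @export
process_document <- function(doc, lexicons,
                             section_patterns = default_section_patterns()) {
  txt <- clean_text(doc$text, lexicons$stop_words)
  if (!is.null(section_patterns)) txt <- select_sections(txt, section_patterns)
  tag_document(raw_document(doc$doc_id, txt, doc$label), lexicons)
}

#' Serialise tagged documents to JSON
#'
#' @param docs list of `glyco_tagged`.
#' @param path output file.
#' @export
write_tagged_documents <- function(docs, path) {
  payload <- lapply(docs, function(d) list(
    doc_id = d$doc_id,
    sentences = lapply(d$sentences, function(s)
      list(tags = s$tags, source_text = s$source_text))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tagged_documents
#' @export
read_tagged_documents <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(d) structure(list(
    doc_id = d$doc_id,
    sentences = lapply(d$sentences, function(s)
      list(tags = unlist(s$tags), source_text = s$source_text))),
    class = "glyco_tagged"))
}
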