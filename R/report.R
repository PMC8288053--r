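#' Count critical keywords in a cleaned document
#'
#' Case-insensitive occurrence counts of protein names, organism names and
#' method terms — the "extracted proteins, species and methods" panel of a
#' curation report. Terms that never occur are omitted.
#'
#' @param text cleaned document text (see [clean_text()]).
#' @param lexicons a `glyco_lexicons`.
#' @return named list with elements `proteins`, `organisms`, `methods`,
#'   each a named integer vector of counts >= 1.
#' @export
count_keywords <- function(text, lexicons) {
  dicts <- list(proteins = lexicons$protein_names,
                organisms = lexicons$organism_names,
                methods = lexicons$word_lists$methods %||% character())
  lapply(dicts, function(terms) {
    counts <- vapply(terms, function(tm) {
      pat <- paste0("\\b", escape_regex(tm), "\\b")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, integer(1))
    counts[counts > 0L]
  })
}

#' Extract presumably informative sentences
#'
#' Returns every retained tag sentence whose tag set contains one of the
#' target tag combinations (subset semantics: the sentence may carry more
#' tags than the target). A sentence is reported once per matched target.
#' The default target is the combination most indicative of a site-mapping
#' claim: `PROTEIN + OGLCNAC + STSITES`.
#'
#' @param tagged a `glyco_tagged` document.
#' @param targets list of character vectors of tags.
#' @return data.frame with columns `source_text`, `tags`, `combination`.
#' @export
informative_sentences <- function(tagged,
                                  targets = list(c("PROTEIN", "OGLCNAC",
                                                   "STSITES"))) {
  stopifnot(length(targets) > 0L)
  rows <- list()
  for (s in tagged$sentences) {
    for (tgt in targets) {
      if (all(tgt %in% s$tags))
        rows[[length(rows) + 1L]] <- data.frame(
          source_text = s$source_text,
          tags = paste(s$tags, collapse = " "),
          combination = paste(tgt, collapse = "+"),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(source_text = character(), tags = character(),
                      combination = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

update_schema <- function() {
  list(
    columns = c("action", "accession", "amino_acid", "position", "pmid", "note"),
    required = list(
      add_protein = c("accession", "pmid"),
      add_site = c("accession", "amino_acid", "position", "pmid"),
      add_reference = c("accession", "pmid"),
      remove = "accession"
    )
  )
}

#' Parse CSV-formatted database update instructions
#'
#' Schema v1: columns `action, accession, amino_acid, position, pmid, note`
#' with `action` one of `add_protein`, `add_site`, `add_reference`,
#' `remove`; lines starting with `#` (including the versioned header
#' written by [update_records_to_csv()]) are ignored. Rows failing
#' validation are never silently dropped: they are collected, with row
#' number and reason, into the `errors` attribute of the result.
#'
#' When protein sequences are supplied, `add_site` rows are additionally
#' cross-checked with [qc_site()] and the flag is recorded in a `qc`
#' column.
#'
#' @param input path to a CSV file, or the CSV content as a character
#'   vector of lines.
#' @param sequences optional named character vector of protein sequences.
#' @return data.frame of valid update records; attribute `errors` is a
#'   data.frame (`row`, `reason`) of rejected rows.
#' @export
parse_update_instructions <- function(input, sequences = NULL) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else unlist(strsplit(input, "\n"))
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines) || !nzchar(trimws(lines[1])))
    stop("missing header row", call. = FALSE)
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  schema <- update_schema()
  if (!all(schema$columns %in% names(df)))
    stop("header must declare columns: ",
         paste(schema$columns, collapse = ", "), call. = FALSE)
  errors <- list()
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    act <- df$action[i]
    if (!act %in% names(schema$required)) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, reason = paste0("unknown action: ", act))
      next
    }
    missing <- schema$required[[act]][
      !nzchar(trimws(as.character(df[i, schema$required[[act]]])))]
    if (length(missing)) {
      errors[[length(errors) + 1L]] <- data.frame(
        row = i, reason = paste0("missing field(s) for ", act, ": ",
                                 paste(missing, collapse = ", ")))
      next
    }
    if (act == "add_site" && is.na(suppressWarnings(as.integer(df$position[i])))) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, reason = "position is not an integer")
      next
    }
    keep[i] <- TRUE
  }
  out <- df[keep, schema$columns, drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(sequences) && nrow(out)) {
    out$qc <- NA_character_
    for (i in which(out$action == "add_site")) {
      if (out$accession[i] %in% names(sequences))
        out$qc[i] <- qc_site(out$accession[i], out$amino_acid[i],
                             as.integer(out$position[i]), sequences)
    }
  }
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), reason = character())
  out
}

#' Serialise update records back to CSV
#'
#' Writes the versioned header comment plus the schema columns, so that
#' [parse_update_instructions()] round-trips records identically.
#'
#' @param records data.frame of update records.
#' @param path optional output path; omitted, the CSV text is returned.
#' @return the path (invisibly) or the CSV content as a character vector.
#' @export
update_records_to_csv <- function(records, path = NULL) {
  cols <- update_schema()$columns
  txt <- c("# glycotriage update instructions v1",
           utils::capture.output(utils::write.csv(records[, cols, drop = FALSE],
                                                  row.names = FALSE)))
  # write.csv quotes strings; normalise to unquoted form for readability
  txt <- gsub('"', "", txt)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Assemble a per-publication curation report
#'
#' The machine-readable counterpart of a reviewer's screen for one
#' publication: the ensemble's aggregated prediction with its confidence
#' interval and three-way call, per-member votes, counted keywords, and
#' sentences matching informative tag combinations.
#'
#' @param doc a `glyco_raw_doc` (raw text; cleaned internally).
#' @param ens a `glyco_ensemble`.
#' @param vocab the `glyco_vocab` the ensemble was trained against.
#' @param lexicons a `glyco_lexicons`.
#' @param targets informative tag combinations (see
#'   [informative_sentences()]).
#' @param z,threshold aggregation settings (see [decide()]).
#' @return an object of class `glyco_report`.
#' @export
curation_report <- function(doc, ens, vocab, lexicons,
                            targets = list(c("PROTEIN", "OGLCNAC", "STSITES")),
                            z = 1.96, threshold = 0.5) {
  tagged <- process_document(doc, lexicons)
  desc <- vectorize(tagged, vocab)
  agg <- decide(predict(ens, desc, z = z), threshold = threshold)
  cleaned <- clean_text(doc$text, lexicons$stop_words)
  structure(list(
    doc_id = doc$doc_id,
    prediction = agg,
    votes = as.integer(attr(agg, "votes")),
    keyword_counts = count_keywords(cleaned, lexicons),
    informative_sentences = informative_sentences(tagged, targets)
  ), class = "glyco_report")
}

#' @export
print.glyco_report <- function(x, ...) {
  cat(sprintf("<glyco_report> %s\n", x$doc_id))
  cat(sprintf("  call: %s  p_hat = %.2f  CI [%.2f, %.2f]\n",
              x$prediction$call, x$prediction$p_hat,
              x$prediction$ci_low, x$prediction$ci_high))
  cat("  informative sentences:", nrow(x$informative_sentences), "\n")
  invisible(x)
}

#' Write a curation report to JSON and Markdown
#'
#' @param report a `glyco_report`.
#' @param path output path without extension; `<path>.json` and
#'   `<path>.md` are written.
#' @return invisibly, the two paths.
#' @export
write_report <- function(report, path) {
  json_path <- paste0(path, ".json")
  md_path <- paste0(path, ".md")
  jsonlite::write_json(list(
    doc_id = report$doc_id,
    prediction = as.list(report$prediction[1, ]),
    votes = report$votes,
    keyword_counts = lapply(report$keyword_counts, as.list),
    informative_sentences = report$informative_sentences
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c(
    sprintf("# Curation report: %s", report$doc_id),
    "",
    sprintf("**Call:** %s (p_hat = %.3f, 95%% CI [%.3f, %.3f], votes %s)",
            report$prediction$call, report$prediction$p_hat,
            report$prediction$ci_low, report$prediction$ci_high,
            paste(report$votes, collapse = "")),
    "", "## Keywords", "")
  for (cat_name in names(report$keyword_counts)) {
    kc <- report$keyword_counts[[cat_name]]
    if (!length(kc)) next
    md <- c(md, sprintf("- **%s**: %s", cat_name,
                        paste(sprintf("%s (%d)", names(kc), kc),
                              collapse = ", ")))
  }
  md <- c(md, "", "## Informative sentences", "")
  if (nrow(report$informative_sentences)) {
    md <- c(md, sprintf("- [%s] %s",
                        report$informative_sentences$combination,
                        report$informative_sentences$source_text))
  } else {
    md <- c(md, "(none)")
  }
  writeLines(md, md_path)
  invisible(c(json = json_path, markdown = md_path))
}
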