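#' Assemble a set of curation lexicons
#'
#' A lexicon set bundles every dictionary the tagger consults: word lists of
#' literal terms grouped by category, regular-expression lists, protein and
#' organism name dictionaries, and stop phrases removed during cleaning.
#' Literal terms are case-folded on construction; matching is
#' case-insensitive throughout.
#'
#' @param word_lists named list of character vectors; one entry per category
#'   (at least `biology`, `glycobiology`, `cells`, `methods` in the shipped
#'   defaults). Terms may be multi-word phrases.
#' @param regex_lists named list of character vectors of Perl-compatible
#'   regular expressions, one entry per category.
#' @param protein_names,organism_names character vectors of literal names.
#' @param stop_words character vector of phrases stripped by [clean_text()].
#' @return an object of class `glyco_lexicons`.
#' @details Category names must be unique across `word_lists` and
#'   `regex_lists`; a literal term claimed by two word-list categories is a
#'   configuration error (the tagger could not assign a unique tag).
#'   Dictionary priority at tagging time is regex lists, then protein names,
#'   then organism names, then word lists.
#' @seealso [default_lexicons()], [tag_document()]
#' @export
lexicons <- function(word_lists, regex_lists,
                     protein_names = character(),
                     organism_names = character(),
                     stop_words = character()) {
  stopifnot(is.list(word_lists), is.list(regex_lists))
  word_lists <- lapply(word_lists, function(x) unique(tolower(trimws(x))))
  word_lists <- lapply(word_lists, function(x) x[nzchar(x)])
  cats <- c(names(word_lists), names(regex_lists))
  if (anyDuplicated(cats))
    stop("category names must be unique across word lists and regex lists",
         call. = FALSE)
  if (any(vapply(regex_lists, function(p) any(!nzchar(p)), logical(1))))
    stop("empty regular-expression pattern", call. = FALSE)
  # ambiguous lexicon: one literal term claimed by two word-list categories
  all_terms <- unlist(word_lists, use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    dup <- unique(all_terms[duplicated(all_terms)])
    stop("ambiguous lexicon: term(s) claimed by two categories: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  obj <- list(
    word_lists = word_lists,
    regex_lists = regex_lists,
    protein_names = unique(tolower(trimws(protein_names))),
    organism_names = unique(tolower(trimws(organism_names))),
    stop_words = unique(tolower(trimws(stop_words)))
  )
  class(obj) <- "glyco_lexicons"
  obj
}

read_term_file <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Load lexicons from a directory of plain-text dictionaries
#'
#' Reads one term-per-line files (`biology.txt`, `glycobiology.txt`,
#' `cells.txt`, `methods.txt`, `proteins.txt`, `organisms.txt`,
#' `stopwords.txt`) and a `regex.yaml` mapping category names to pattern
#' lists. Lines starting with `#` are comments.
#'
#' @param dir directory containing the dictionary files.
#' @return a `glyco_lexicons` object.
#' @export
read_lexicons <- function(dir) {
  need <- c("biology.txt", "glycobiology.txt", "cells.txt", "methods.txt",
            "proteins.txt", "organisms.txt", "stopwords.txt", "regex.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing lexicon file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  wl <- lapply(c(biology = "biology.txt", glycobiology = "glycobiology.txt",
                 cells = "cells.txt", methods = "methods.txt"),
               function(f) read_term_file(file.path(dir, f)))
  rx <- yaml::read_yaml(file.path(dir, "regex.yaml"))
  rx <- lapply(rx, as.character)
  lexicons(
    word_lists = wl,
    regex_lists = rx,
    protein_names = read_term_file(file.path(dir, "proteins.txt")),
    organism_names = read_term_file(file.path(dir, "organisms.txt")),
    stop_words = read_term_file(file.path(dir, "stopwords.txt"))
  )
}

#' Shipped default lexicons
#'
#' The defaults bundled with the package: a compact reconstruction of the
#' category dictionaries used for O-GlcNAc literature triage (biology,
#' glycobiology, cell, and method word lists; regular expressions for
#' O-GlcNAc, phosphorylation, Ser/Thr sites, amino acids, peptides, nucleic
#' acids, pronominial, conclusion and description vocabulary; protein and
#' organism name dictionaries; stop phrases). They are ordinary text files
#' under `system.file("extdata/lexicons", package = "glycotriage")` and are
#' meant to be replaced or extended by users with domain-specific lists.
#'
#' @return a `glyco_lexicons` object.
#' @export
default_lexicons <- function() {
  read_lexicons(system.file("extdata", "lexicons", package = "glycotriage"))
}

#' @export
print.glyco_lexicons <- function(x, ...) {
  cat("<glyco_lexicons>\n")
  cat("  word lists:  ",
      paste(sprintf("%s (%d)", names(x$word_lists),
                    lengths(x$word_lists)), collapse = ", "), "\n")
  cat("  regex lists: ",
      paste(sprintf("%s (%d)", names(x$regex_lists),
                    lengths(x$regex_lists)), collapse = ", "), "\n")
  cat(sprintf("  proteins: %d  organisms: %d  stop phrases: %d\n",
              length(x$protein_names), length(x$organism_names),
              length(x$stop_words)))
  invisible(x)
}

default_section_patterns <- function() {
  path <- system.file("extdata", "lexicons", "sections.yaml",
                      package = "glycotriage")
  yaml::read_yaml(path)
}
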