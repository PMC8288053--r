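AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased and checked against the 20 standard one-letter
#' amino-acid codes; ambiguous or non-standard residues (B, J, Z, X, U, O)
#' are rejected with an error rather than silently coerced. The accession
#' is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names = accessions).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`,
                        character(1), 1L)
  bad <- vapply(seqs, function(s)
    any(!strsplit(s, "")[[1]] %in% AA20), logical(1))
  if (any(bad))
    stop("non-standard amino-acid code(s) in: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate accessions in FASTA", call. = FALSE)
  seqs
}

#' Read PTM site annotations
#'
#' CSV or TSV (by file extension) with columns `accession`, `amino_acid`,
#' `position` (1-based).
#'
#' @param path annotation file.
#' @return data.frame with the three columns, positions as integers.
#' @export
read_site_annotations <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("accession", "amino_acid", "position")
  if (!all(need %in% names(x)))
    stop("site table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x$position <- as.integer(x$position)
  x$amino_acid <- toupper(x$amino_acid)
  x
}

#' Quality-control a claimed modification site against its protein sequence
#'
#' A site passes QC when its 1-based position falls inside the sequence,
#' the sequence letter at that position equals the claimed residue, and the
#' residue is serine or threonine — the only amino acids targeted by
#' O-GlcNAcylation. Checks are ordered: `out_of_range` before
#' `residue_mismatch` before `not_ser_thr`.
#'
#' @param accession protein accession of the claim.
#' @param amino_acid claimed one-letter residue.
#' @param position claimed 1-based position.
#' @param sequences named character vector of sequences (e.g. from
#'   [read_protein_fasta()]); must contain `accession`.
#' @return one of `"ok"`, `"out_of_range"`, `"residue_mismatch"`,
#'   `"not_ser_thr"`.
#' @export
qc_site <- function(accession, amino_acid, position, sequences) {
  if (!accession %in% names(sequences))
    stop("no sequence for accession ", accession, call. = FALSE)
  seq <- sequences[[accession]]
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > nchar(seq))
    return("out_of_range")
  actual <- substr(seq, position, position)
  if (!identical(actual, toupper(amino_acid))) return("residue_mismatch")
  if (!actual %in% c("S", "T")) return("not_ser_thr")
  "ok"
}

#' @rdname qc_site
#' @param sites data.frame with columns `accession`, `amino_acid`,
#'   `position`.
#' @return `qc_sites()`: the input data.frame with an added `flag` column.
#' @export
qc_sites <- function(sites, sequences) {
  sites$flag <- vapply(seq_len(nrow(sites)), function(i)
    qc_site(sites$accession[i], sites$amino_acid[i], sites$position[i],
            sequences), character(1))
  sites
}

protease_rule <- function(protease, custom_rule = NULL) {
  if (protease == "trypsin")
    return(list(cleave_after = c("K", "R"), blocked_next = "P"))
  if (protease == "custom") {
    if (is.null(custom_rule))
      stop("custom protease requires a custom_rule", call. = FALSE)
    return(list(cleave_after = toupper(custom_rule$cleave_after),
                blocked_next = toupper(custom_rule$blocked_next %||% character())))
  }
  stop("unknown protease: ", protease, call. = FALSE)
}

#' In-silico protease digestion
#'
#' Full digestion returns the unique maximal cleavage partition: peptides
#' between consecutive cleavage points, tiling the sequence with no gaps or
#' overlaps. Partial digestion additionally returns every peptide spanning
#' up to `max_missed` internal (uncut) cleavage sites. The default trypsin
#' rule cleaves C-terminal to K or R except when the next residue is
#' proline.
#'
#' @param sequence protein sequence (one-letter codes) or a single named
#'   element of the vector returned by [read_protein_fasta()].
#' @param accession accession recorded in the output (defaults to the
#'   sequence's name, if any).
#' @param protease `"trypsin"` or `"custom"`.
#' @param mode `"full"` or `"partial"`.
#' @param max_missed maximum missed cleavages (partial mode; full mode
#'   forces 0).
#' @param custom_rule list with `cleave_after` (residues cut after) and
#'   optional `blocked_next` (residues blocking the cut when next).
#' @return data.frame with columns `accession`, `start`, `end`, `peptide`,
#'   `missed_cleavages`; coordinates are 1-based closed intervals.
#' @export
digest_protein <- function(sequence, accession = NULL, protease = "trypsin",
                           mode = c("full", "partial"), max_missed = 0L,
                           custom_rule = NULL) {
  mode <- match.arg(mode)
  accession <- accession %||% names(sequence) %||% "protein"
  sequence <- toupper(unname(sequence))
  stopifnot(nchar(sequence) >= 1L)
  rule <- protease_rule(protease, custom_rule)
  if (mode == "full") max_missed <- 0L
  assert_scalar_number(max_missed, "max_missed", lower = 0)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% rule$cleave_after)
  cut_after <- cut_after[cut_after < n & !chars[pmin(cut_after + 1L, n)] %in%
                           rule$blocked_next]
  bounds <- c(0L, cut_after, n)
  starts <- utils::head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  k <- length(starts)
  rows <- list()
  for (i in seq_len(k)) {
    for (j in i:min(k, i + max_missed)) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = accession, start = starts[i], end = ends[j],
        peptide = substr(sequence, starts[i], ends[j]),
        missed_cleavages = j - i, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Positional consensus matrix around modification sites
#'
#' Aligns the `-w..+w` flanking windows of validated sites and tallies, for
#' each offset, the frequency of each of the 20 amino acids. Offsets that
#' fall outside a protein's termini contribute nothing to their column.
#' Column information content is `log2(20) - H` with `H` the Shannon
#' entropy of the column's frequencies — the heights used in sequence
#' logos. Sites failing [qc_site()] are excluded with a warning; an empty
#' valid-site list is an error.
#'
#' @param sites data.frame with `accession`, `amino_acid`, `position`.
#' @param sequences named character vector of protein sequences.
#' @param half_window window half-width `w` (default 5).
#' @return an object of class `glyco_consensus`: `offsets`, `counts` and
#'   `freqs` (20 x 2w+1 matrices), `info_content` (bits per offset),
#'   `n_sites`.
#' @export
consensus_matrix <- function(sites, sequences, half_window = 5L) {
  assert_scalar_number(half_window, "half_window", lower = 1)
  flagged <- qc_sites(sites, sequences)
  bad <- flagged$flag != "ok"
  if (any(bad)) {
    warning(sum(bad), " site(s) failed QC and were excluded from the consensus")
    flagged <- flagged[!bad, , drop = FALSE]
  }
  if (!nrow(flagged)) stop("no valid sites for consensus", call. = FALSE)
  w <- as.integer(half_window)
  offsets <- -w:w
  counts <- matrix(0L, nrow = 20L, ncol = length(offsets),
                   dimnames = list(AA20, offsets))
  for (i in seq_len(nrow(flagged))) {
    seq <- sequences[[flagged$accession[i]]]
    pos <- flagged$position[i] + offsets
    inside <- pos >= 1L & pos <= nchar(seq)
    res <- substring(seq, pos[inside], pos[inside])
    for (j in seq_along(res))
      counts[res[j], which(inside)[j]] <- counts[res[j], which(inside)[j]] + 1L
  }
  totals <- colSums(counts)
  freqs <- sweep(counts, 2L, pmax(totals, 1L), `/`)
  freqs[, totals == 0L] <- NA_real_
  info <- apply(freqs, 2L, function(f) {
    if (anyNA(f)) return(NA_real_)
    nz <- f[f > 0]
    log2(20) + sum(nz * log2(nz))
  })
  structure(list(offsets = offsets, counts = counts, freqs = freqs,
                 info_content = info, n_sites = nrow(flagged)),
            class = "glyco_consensus")
}

#' @export
print.glyco_consensus <- function(x, ...) {
  cat(sprintf("<glyco_consensus> %d site(s), offsets %d..%d\n",
              x$n_sites, min(x$offsets), max(x$offsets)))
  print(round(x$info_content, 3))
  invisible(x)
}

#' Plot the information-content profile of a consensus matrix
#'
#' A compact stand-in for a full sequence logo: per-offset information
#' content in bits, with the dominant residue lettered on each bar.
#'
#' @param x a `glyco_consensus`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.glyco_consensus <- function(x, ...) {
  h <- ifelse(is.na(x$info_content), 0, x$info_content)
  bp <- graphics::barplot(h, names.arg = x$offsets,
                          ylab = "information (bits)",
                          xlab = "offset from site", ylim = c(0, log2(20)),
                          ...)
  top <- rownames(x$freqs)[apply(x$freqs, 2L, which.max)]
  graphics::text(bp, h, labels = top, pos = 3, cex = 0.8)
  invisible(x)
}

#' Write a consensus matrix as CSV
#'
#' Long-format table: offset, residue, count, frequency, plus a per-offset
#' information-content column.
#'
#' @param x a `glyco_consensus`.
#' @param path output CSV.
#' @export
write_consensus_csv <- function(x, path) {
  df <- expand.grid(residue = rownames(x$counts), offset = x$offsets,
                    stringsAsFactors = FALSE)
  df$count <- as.vector(x$counts)
  df$frequency <- as.vector(x$freqs)
  df$info_content <- rep(x$info_content, each = nrow(x$counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classify O-GlcNAc / phosphorylation site overlap
#'
#' Partitions the union of the two position sets: positions reported only
#' O-GlcNAcylated, only phosphorylated, or both ("dual" sites, the crosstalk
#' residues highlighted in protein views).
#'
#' @param oglcnac_sites,phospho_sites integer vectors of 1-based positions.
#' @return named character vector over the sorted union of positions with
#'   values `"oglcnac"`, `"phospho"` or `"dual"`.
#' @export
classify_ptm_overlap <- function(oglcnac_sites, phospho_sites) {
  og <- unique(as.integer(oglcnac_sites))
  ph <- unique(as.integer(phospho_sites))
  all_pos <- sort(union(og, ph))
  out <- ifelse(all_pos %in% og & all_pos %in% ph, "dual",
                ifelse(all_pos %in% og, "oglcnac", "phospho"))
  names(out) <- all_pos
  out
}
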