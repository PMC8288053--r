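fixture_fasta <- function() {
  system.file("extdata", "example", "synthetic_proteins.fasta",
              package = "glycotriage")
}

test_that("FASTA loading validates the amino-acid alphabet", {
  seqs <- read_protein_fasta(fixture_fasta())
  expect_named(seqs, c("SYN0001", "SYN0002"))
  expect_equal(nchar(seqs[["SYN0001"]]), 20L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">BAD1 has ambiguous residues", "MSTXAVB"), bad)
  expect_error(read_protein_fasta(bad), "non-standard")
})

test_that("site QC distinguishes ok, mismatch, out-of-range and non-S/T", {
  seqs <- c(P1 = "MSTA")
  expect_equal(qc_site("P1", "S", 2, seqs), "ok")
  expect_equal(qc_site("P1", "T", 3, seqs), "ok")
  expect_equal(qc_site("P1", "T", 4, seqs), "residue_mismatch")  # 4 is A
  expect_equal(qc_site("P1", "S", 9, seqs), "out_of_range")
  expect_equal(qc_site("P1", "S", 0, seqs), "out_of_range")
  expect_equal(qc_site("P1", "M", 1, seqs), "not_ser_thr")
  expect_error(qc_site("P9", "S", 2, seqs), "no sequence")
})

test_that("QC flags exactly the planted errors on a synthetic site table", {
  set.seed(61)
  seqs <- setNames(vapply(1:5, function(i) random_aa_sequence(60),
                          character(1)), paste0("P", 1:5))
  # valid S/T sites
  sites <- do.call(rbind, lapply(names(seqs), function(a) {
    st <- which(strsplit(seqs[[a]], "")[[1]] %in% c("S", "T"))
    st <- head(st, 4)
    data.frame(accession = a,
               amino_acid = substring(seqs[[a]], st, st),
               position = st, stringsAsFactors = FALSE)
  }))
  # plant k errors at known rows
  planted <- c(3, 7, 11)
  sites$amino_acid[planted[1]] <- setdiff(c("S", "T"),
                                          sites$amino_acid[planted[1]])[1]
  sites$position[planted[2]] <- 1000L
  ok_not_st <- which(strsplit(seqs[["P1"]], "")[[1]] == "A")[1]
  sites$accession[planted[3]] <- "P1"
  sites$amino_acid[planted[3]] <- "A"
  sites$position[planted[3]] <- ok_not_st
  flagged <- qc_sites(sites, seqs)
  expect_equal(which(flagged$flag != "ok"), planted)
  expect_equal(flagged$flag[planted],
               c("residue_mismatch", "out_of_range", "not_ser_thr"))
})

test_that("tryptic digestion reproduces the hand-worked fixture", {
  full <- digest_protein("MKRPAKASR", accession = "X", mode = "full")
  expect_equal(full$peptide, c("MK", "RPAK", "ASR"))
  expect_equal(full$start, c(1L, 3L, 7L))
  expect_equal(full$end, c(2L, 6L, 9L))
  expect_true(all(full$missed_cleavages == 0L))
  # full-mode peptides concatenate back to the sequence
  expect_equal(paste(full$peptide, collapse = ""), "MKRPAKASR")

  partial <- digest_protein("MKRPAKASR", mode = "partial", max_missed = 1)
  added <- setdiff(partial$peptide, full$peptide)
  expect_setequal(added, c("MKRPAK", "RPAKASR"))
  expect_equal(nrow(partial), 5L)

  # no cleavage sites (no K/R): the whole sequence is one peptide
  none <- digest_protein("MAGICPEPTIDE", mode = "full")
  expect_equal(nrow(none), 1L)
  expect_equal(none$peptide, "MAGICPEPTIDE")
  # a terminal K/R produces no extra cut
  expect_equal(digest_protein("MAK", mode = "full")$peptide, "MAK")
})

test_that("digestion equals brute-force enumeration on random sequences", {
  set.seed(17)
  for (i in 1:20) {
    seqn <- random_aa_sequence(sample(20:200, 1))
    for (mm in 0:2) {
      got <- digest_protein(seqn, mode = if (mm == 0) "full" else "partial",
                            max_missed = mm)
      want <- brute_digest(seqn, mm)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$missed_cleavages, want$missed)
    }
    full <- digest_protein(seqn, mode = "full")
    expect_equal(paste(full$peptide, collapse = ""), seqn)
  }
})

test_that("custom protease rules and errors behave", {
  # cleave after D, no blocking
  got <- digest_protein("MADGDPK", protease = "custom",
                        custom_rule = list(cleave_after = "D"))
  expect_equal(got$peptide, c("MAD", "GD", "PK"))
  expect_error(digest_protein("MK", protease = "lysc"), "unknown protease")
  expect_error(digest_protein("MK", protease = "custom"), "custom_rule")
})

test_that("consensus matrices tally flanking residues exactly", {
  seqs <- c(A = "AAASAAA", B = "CCCSCCC")
  sites <- data.frame(accession = c("A", "B"), amino_acid = "S",
                      position = 4L)
  cm <- consensus_matrix(sites, seqs, half_window = 3)
  expect_equal(dim(cm$counts), c(20L, 7L))
  # every column saw both sequences
  expect_true(all(colSums(cm$counts) == 2L))
  expect_true(all(abs(colSums(cm$freqs) - 1) < 1e-12))
  # centre column: S at frequency 1 -> full information
  centre <- which(cm$offsets == 0)
  expect_equal(cm$freqs["S", centre], 1.0)
  expect_equal(cm$info_content[[centre]], log2(20), tolerance = 1e-12)
  # flank columns: A and C at 0.5 each -> log2(20) - 1 bits
  expect_equal(unname(cm$freqs["A", 1]), 0.5)
  expect_equal(cm$info_content[[1]], log2(20) - 1, tolerance = 1e-12)
})

test_that("single-site consensus has full information; duplication leaves frequencies unchanged", {
  seqs <- c(A = "MKSTRLV")
  one <- data.frame(accession = "A", amino_acid = "T", position = 4L)
  cm1 <- consensus_matrix(one, seqs, half_window = 2)
  expect_true(all(abs(cm1$info_content - log2(20)) < 1e-12))
  two <- rbind(one, one)
  cm2 <- consensus_matrix(two, seqs, half_window = 2)
  expect_equal(cm2$freqs, cm1$freqs)
  expect_equal(cm2$counts, 2L * cm1$counts)
})

test_that("consensus windows clip at protein termini and QC-filter sites", {
  seqs <- c(A = "STAAA")
  sites <- data.frame(accession = "A", amino_acid = c("S", "S"),
                      position = c(1L, 4L))  # position 4 is A: mismatch
  expect_warning(cm <- consensus_matrix(sites, seqs, half_window = 2),
                 "failed QC")
  expect_equal(cm$n_sites, 1L)
  # offsets -2 and -1 fall before the N-terminus: empty columns
  expect_true(all(cm$counts[, 1:2] == 0L))
  expect_true(all(is.na(cm$freqs[, 1])))
  expect_true(is.na(cm$info_content[[1]]))

  bad <- data.frame(accession = "A", amino_acid = "S", position = 4L)
  expect_warning(expect_error(consensus_matrix(bad, seqs, 2), "no valid"))
})

test_that("consensus CSV export carries counts, frequencies and information", {
  seqs <- read_protein_fasta(fixture_fasta())
  sites <- read_site_annotations(
    system.file("extdata", "example", "synthetic_sites.csv",
                package = "glycotriage"))
  cm <- consensus_matrix(sites, seqs, half_window = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_consensus_csv(cm, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), 20L * 7L)
  expect_equal(sum(got$count), sum(cm$counts))
})

test_that("PTM overlap classification partitions the union of sites", {
  expect_equal(classify_ptm_overlap(c(2, 5), c(5, 9)),
               c(`2` = "oglcnac", `5` = "dual", `9` = "phospho"))
  expect_false(any(classify_ptm_overlap(1:3, 4:6) == "dual"))
  expect_true(all(classify_ptm_overlap(c(7, 8), c(7, 8)) == "dual"))
  expect_length(classify_ptm_overlap(integer(), integer()), 0L)
})
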