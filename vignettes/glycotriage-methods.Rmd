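---
title: "Methods: literature triage and site bookkeeping in glycotriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature triage and site bookkeeping in glycotriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotriage)
```

## The triage problem

A curated *O*-GlcNAc resource needs to decide, for every candidate
publication, whether it experimentally demonstrates protein
*O*-GlcNAcylation (a *positive*) or not (a *negative*), and then hand a
human curator the extracted evidence. Scientific prose is far too variable
to classify directly at desk-scale sample sizes, so the engine first
collapses each document into a small discrete alphabet and only then
trains a classifier. This vignette explains each stage, the parameters
that matter, and the design decisions taken where more than one
reasonable choice existed.

## Text processing

`clean_text()` applies three removal rules to converted publication text:
spans inside parentheses, brackets or braces are deleted (iterating until
no bracketed span remains, so nesting vanishes); every character that is
not alphanumeric, whitespace or a period is deleted outright; and stop
phrases (journal boilerplate, affiliation vocabulary) are removed
case-insensitively after themselves being cleaned by the same rules.
Character deletion is literal — neighbours merge, so `O-GlcNAc` becomes
`OGlcNAc` — and the shipped regular expressions therefore match
hyphen-free, case-folded variants. All whitespace is normalised to single
spaces first: converted text is full of arbitrary line breaks, and
deleting them (rather than spacing them) would merge unrelated words. The
function is idempotent, which the test suite checks by property.

`select_sections()` keeps the text spans opened by Results/Discussion
headers and closed by the next recognised header. Header patterns are
matched case-*sensitively* against Title-case and ALL-CAPS forms: ordinary
prose ("these results show...") must not be mistaken for a section
boundary, and true headers retain capitalisation through cleaning. Because
layout-based PDF conversion frequently destroys headers, the function
falls back to the whole document when no keep-header is found — losing
selectivity is recoverable downstream, losing the Results section is not.

`tag_document()` replaces dictionary matches with uppercase category tags
and drops everything else. Matching is case-insensitive, left-to-right and
longest-match-wins; when two dictionaries claim the same span, priority is
fixed: regular-expression lists, then protein names, then organism names,
then word lists. A literal term claimed by two word-list categories is a
configuration error, not a silent choice. Only period-delimited segments
with **more than one tag** survive; a lone tag carries no combinatorial
information. The shipped dictionaries under
`system.file("extdata/lexicons", package = "glycotriage")` are a compact
reconstruction intended for testing and as a template — production use
should substitute full UniProtKB-derived protein/organism lists, which is
why every dictionary loads from plain editable text files.

## Features and splits

An *expression* is a retained tag sentence rendered as its space-joined
tag chain. `build_vocabulary()` keeps expressions whose occurrence count
over the **concatenated training corpus** (not per document) reaches
`min_count = 4`; rarer chains are more likely conversion artifacts than
reproducible signal, and a presence threshold fixed on training documents
only avoids leaking held-out information into the feature space.
Expressions are sorted in the C locale so descriptor indices are stable
across machines. `vectorize()` is strictly binary — presence or absence,
never counts or weights — because at a few hundred training documents
per class, richer encodings mostly add variance.

`make_splits()` shuffles and slices the labelled pool into
train/test/validation halves and quarters (a balanced pool of 1340 gives
670/335/335) and accepts a candidate split only when every set satisfies
|n_pos − n_neg| / n < 0.01, approximating a binomial label distribution
per set. The comparison is strict, and the criterion is evaluated
per-set: a jointly-balanced split with one skewed set would still bias
early stopping. Note the arithmetic consequence: sets smaller than 100
can never satisfy the rule unless perfectly balanced (1/n ≥ 0.01), so
desk-scale tests pass an explicit, larger `balance_tol`; the rule is
exercised at its default on 1340-identifier pools. Splitting takes an
explicit seed for reproducibility; seedless mode reproduces the original
unseeded-shuffle protocol.

## The classifier

Each ensemble member is a feed-forward network: `p` binary inputs, one
hidden layer of ReLU units (default 96), and **two independent sigmoid
output units** encoding (evidence present, evidence absent) — not a
softmax; the pair is not constrained to sum to 1. Labels encode positive
→ (1,0) and negative → (0,1).

Choices the architecture description leaves open were resolved as
follows, and are flagged as this package's choices:

- **Loss**: mean binary cross-entropy over the two sigmoid units, the
  canonical pairing for a logistic binary classifier. Predictions are
  clipped to [ε, 1−ε], ε = 10⁻¹², before the logarithm.
- **Optimiser**: full-batch gradient descent, no momentum — nothing
  beyond backpropagation plus the learning-rate schedule.
- **Initialisation**: uniform U(−r, r) with r = √(6/fan-in), the standard
  scaling for ReLU layers; biases start at zero.
- **Dropout semantics**: the dropout parameter 0.7 is read as the
  *retention* probability, implemented as inverted dropout (kept hidden
  units scaled by 1/keep at train time, so expected train-mode activation
  equals eval-mode activation; verified by Monte-Carlo test). The
  alternative reading is available via `dropout_semantics = "drop"`.
  `dropout = 0` disables masking entirely. One fresh mask is drawn per
  epoch and shared across the full batch.
- **Ties**: an output pair with exactly equal probabilities is called
  negative — the conservative direction for triage, where a false
  positive costs curator time.

The learning rate cycles: lr(e) = ilr · d^⌊e/c⌋ · exp(−k · (e mod c))
with defaults ilr = 0.25, k = 0.05 per epoch, c = 100 epochs and
d = 0.95 per cycle — an exponential decay within each cycle that restarts
at a peak reduced by 5% each cycle, reconstructed as a closed form from
the four named constants. Within a cycle the rate is strictly decreasing
(k > 0) and peaks strictly decrease across cycles (d < 1).

Training always runs the full n_cycles × c = 1000 epochs; *early
stopping* selects, rather than halts: the parameter snapshot from the
epoch with the highest test-set accuracy (earliest epoch on ties) is what
`nn_train()` returns, together with the complete per-epoch trace. A
non-finite loss aborts with a diagnostic pointing at learning-rate
divergence.

Backpropagation is exact; the suite compares every gradient entry with
central finite differences (step 10⁻⁵) at relative error < 10⁻⁵ over 100
random configurations. Random fixtures avoid the measure-zero ReLU kink
(an all-zero input row with zero biases), where the one-sided derivative
makes finite differences ill-defined.

## Bagging and decisions

Five members train on independent half-size subsets of the training set
(shuffle-and-slice without replacement within a subset — not a classical
with-replacement bootstrap) against the shared test set for early
stopping. At prediction time each member casts a binary vote (positive
unit ≥ negative unit); treating votes as Bernoulli trials justifies the
binomial interval p̂ ± z·√(p̂(1−p̂)/n) with z = 1.96. Averaging raw
probabilities is available behind `type = "prob"` but forfeits the
binomial reading. Displayed interval bounds are truncated to [0, 1];
the *decision width*, however, is the distance between the untruncated
limits — with five voters, 3/5 votes give width 0.859 and 4/5 give
0.701, both above the 0.5 ambiguity threshold, so only unanimous votes
are decisive at n = 5. The threshold comparison is strict: width exactly
0.5 is decisive.

With the truth known, an aggregated prediction is *correct* when p̂
rounded to the nearest integer matches the label (p̂ = 0.5 rounds to
negative); otherwise it is *ambiguous* when the interval width exceeds
0.5 — a curator reviewing flagged items can rescue it — and *wrong*
when the interval is narrow. `accuracy_with_ambiguous` counts correct
plus ambiguous outcomes and therefore never falls below `accuracy`.
Precision and recall are computed on the positive class over decisive
calls only; with no decisive positive call, precision is reported absent
(`NA`), never zero.

## The synthetic corpus and its Bayes oracle

`generate_corpus()` emulates a labelled triage corpus at the tag-sentence
level: `n_signal_patterns` discriminative tag chains appear in positive
documents with probability `p_signal_pos` and in negatives with
`p_signal_neg`; label-independent background patterns (inclusion 0.5) and
single-tag fillers (discarded by the >1-tag rule) add realistic clutter.
An optional surface mode realises each tag as a default-lexicon term glued
with untagged filler words, exercising the full cleaning/tagging path; the
tests verify that the recovered tag sentences equal the planted ones,
document by document.

Because background and filler are label-independent, the optimal
classifier observes only the 2^s presence configurations of the signal
patterns, and `bayes_accuracy()` enumerates them exactly (refusing s > 12).
This gives the two calibration points the acceptance properties use: a
deterministic signal (1/0) must be recovered at ≥ 0.99 held-out accuracy,
and no trained model may beat the enumerated bound by more than sampling
noise on a noisy signal.

Defaults — 200 documents, balanced classes, 5 signal patterns at 0.9/0.1,
20 background patterns, 8–20 sentences per document — are a desk-scale
analogue of a real curation corpus (about 1300 documents, balanced by
construction). What the generator does **not** emulate is scientific
English itself: real tag-sentence distributions are long-tailed and
pattern occurrences are correlated within a paper, so passing tests bound
implementation correctness, not expected performance on real literature.
The replicate studies in the test suite use 3 training cycles per member
(300 epochs) on these 200-document corpora; the schedule defaults remain
10 cycles.

## Sequence-side utilities

Coordinates are 1-based, fully closed intervals, following UniProt
convention. `qc_site()` checks range, then residue identity, then Ser/Thr
targeting — the only residues O-GlcNAc modifies — and reports the first
failure. Sites failing QC are excluded from consensus building with a
warning rather than aborting, matching a self-maintaining pipeline that
must keep running on partially dirty data; sequences with ambiguous
residue codes (B, J, Z, X, U, O) are instead rejected at load, because a
silent coercion there would corrupt every downstream count.

`digest_protein()` implements the standard trypsin rule (cleave C-terminal
to K or R except before P) plus custom rules; full mode returns the
maximal cleavage partition (peptides provably tile the sequence), partial
mode every peptide spanning at most `max_missed` internal sites. The
implementation is checked against a brute-force enumeration oracle on
random sequences. `consensus_matrix()` tallies residues at offsets −w..+w
around validated sites; offsets beyond a protein's termini contribute
nothing to their column, per-column frequencies sum to 1 wherever counts
exist, and information content log₂(20) − H (bits) gives sequence-logo
heights, with the single-observation column pinned at log₂(20) ≈ 4.32
bits.

## Curation reports and updates

`curation_report()` bundles what a reviewer needs per publication: the
aggregated prediction with votes and interval, per-term keyword counts
(proteins, organisms, methods; case-insensitive, zero counts omitted), and
sentences whose tag sets contain a target combination (subset semantics;
default `PROTEIN+OGLCNAC+STSITES`). The update-instruction schema
(`action, accession, amino_acid, position, pmid, note`, versioned header
comment) is this package's own minimal definition — only "simple
CSV-formatted instructions" is specified by the workflow it mirrors.
Malformed rows are never silently dropped; they are collected with row
numbers and reasons, and `add_site` rows are cross-checked by `qc_site()`
when sequences are supplied.

## Known limitations

- The shipped lexicons are reconstructions; tagging quality on real
  publications depends mainly on the protein/organism dictionaries, which
  should be regenerated from UniProtKB for production use.
- With five voters and z = 1.96 every non-unanimous vote is ambiguous;
  the binomial normal approximation is crude at n = 5 (its nominal
  coverage is verified in the regime n = 100), and z is configurable for
  that reason.
- Section selection assumes headers survive conversion with their
  capitalisation; documents converted to lower case fall back to
  whole-document tagging.
- `run_pipeline()` holds all descriptor matrices in memory; at the
  intended corpus scale (10³–10⁴ documents, ~10³ features) this is a few
  megabytes.
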