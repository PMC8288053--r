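Package: glycotriage
Title: Literature Triage and Site Bookkeeping for O-GlcNAc Curation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A semi-automated curation engine for protein O-GlcNAcylation
    databases. Publications rendered as plain text are reduced to sentences of
    category tags using lexicon and regular-expression dictionaries, encoded as
    binary presence vectors over a tag-pattern vocabulary, and classified by a
    bagged ensemble of from-scratch feed-forward neural networks with dropout,
    a cyclical learning-rate schedule and early stopping; aggregated votes
    carry a binomial confidence interval that routes ambiguous calls to human
    review. Companion utilities validate claimed modification sites against
    protein sequences, perform in-silico protease digestion with missed
    cleavages, build position-frequency consensus matrices for sequence logos,
    classify O-GlcNAc/phosphorylation dual sites, and assemble per-publication
    curation reports. A synthetic-corpus generator with controllable planted
    class signal makes every stage testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
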