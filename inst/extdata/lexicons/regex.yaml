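# regular-expression dictionaries, applied case-insensitively to cleaned text
# (cleaning deletes punctuation, so patterns match hyphen-free variants:
#  "O-GlcNAc" arrives as "OGlcNAc"). Category name = tag emitted.
oglcnac:
  - "\\boglcnac\\w*"
  - "\\bglcnacylat\\w*"
  - "\\bnacetylglucosamine\\b"
phospho:
  - "\\bphospho\\w*"
  - "\\bdephosphorylat\\w*"
  - "\\bkinases?\\b"
  - "\\bphosphatases?\\b"
stsites:
  - "\\b(?:ser|thr)\\d{1,4}\\b"
  - "\\b[st]\\d{1,4}\\b"
aminoacids:
  - "\\b(?:alanine|arginine|asparagine|aspartate|cysteine|glutamine|glutamate|glycine|histidine|isoleucine|leucine|lysine|methionine|phenylalanine|proline|serines?|threonines?|tryptophan|tyrosine|valine)\\b"
  - "\\b(?:ala|arg|asn|asp|cys|gln|glu|gly|his|ile|leu|lys|met|phe|pro|trp|tyr|val)\\b"
peptides:
  - "\\bglycopeptides?\\b"
  - "\\bpeptides?\\b"
  - "\\btryptic\\b"
  - "\\bdigests?(?:ed|ion)?\\b"
nucleicacids:
  - "\\b(?:dna|rna|mrna|sirna|shrna|cdna|plasmids?|oligonucleotides?)\\b"
pronominial:
  - "\\bwe\\b"
  - "\\bour\\b"
  - "\\bhere(?:in)?\\b"
  - "\\bthis study\\b"
  - "\\bthese (?:results|data|findings)\\b"
conclusion:
  - "\\bconclud\\w+"
  - "\\bdemonstrat\\w+"
  - "\\bconfirm\\w+"
  - "\\bestablish\\w+"
  - "\\breveal\\w+"
  - "\\bindicat\\w+"
  - "\\bsuggest\\w+"
  - "\\bshow(?:s|ed|n)?\\b"
description:
  - "\\bobserv\\w+"
  - "\\bdetect\\w+"
  - "\\bidentif\\w+"
  - "\\bmeasur\\w+"
  - "\\bquantif\\w+"
  - "\\bincreas\\w+"
  - "\\bdecreas\\w+"
  - "\\breduc\\w+"
  - "\\babolish\\w+"
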