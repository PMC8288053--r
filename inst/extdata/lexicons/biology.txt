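# word list: general molecular biology vocabulary (one term per line,
# case-folded; multi-word phrases allowed)
protein
proteins
gene
genes
enzyme
enzymes
substrate
substrates
residue
residues
mutation
mutant
mutants
signaling
pathway
nuclear
cytoplasmic
binding
domain
stability
degradation
transcription
translation
expression
overexpression
knockdown
knockout
interaction
localization
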