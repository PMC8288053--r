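# dictionary: organism names (stand-in for a UniProtKB-derived list)
human
homo sapiens
mouse
mus musculus
rat
rattus norvegicus
rabbit
drosophila
drosophila melanogaster
caenorhabditis elegans
arabidopsis
arabidopsis thaliana
zebrafish
danio rerio
yeast
saccharomyces cerevisiae
escherichia coli
xenopus
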