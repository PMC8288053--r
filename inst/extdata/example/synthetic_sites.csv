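accession,amino_acid,position,source
SYN0001,S,2,synthetic
SYN0001,T,3,synthetic
SYN0001,S,10,synthetic
SYN0002,T,10,synthetic
SYN0002,S,15,synthetic
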