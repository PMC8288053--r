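# dictionary: protein names (stand-in for a UniProtKB-derived list)
tau
p53
ogt
oga
akt
gsk3
foxo1
snap29
crtc2
cmyc
myc
tab1
nup62
sp1
ezh2
tet2
hcf1
synapsin
vimentin
keratin
crystallin
ampk
ikkb
nfkb
caseinkinase
histone h3
histone h2b
alpha synuclein
amyloid precursor protein
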