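# word list: experimental methods
western blot
western blotting
immunoblot
immunoblotting
immunoprecipitation
coimmunoprecipitation
mass spectrometry
lcmsms
maldi
electrophoresis
chromatography
mutagenesis
site directed mutagenesis
click chemistry
metabolic labeling
radiolabeling
flow cytometry
immunofluorescence
microscopy
transfection
pulldown
crispr
elisa
autoradiography
galt labeling
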