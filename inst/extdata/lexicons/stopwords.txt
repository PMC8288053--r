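# stop phrases removed after character cleaning (journals, boilerplate,
# affiliation vocabulary typical of PDF conversion artifacts)
all rights reserved
rights reserved
elsevier
springer
wiley
copyright
creative commons
journal of biological chemistry
nature communications
proceedings of the national academy of sciences
department of biochemistry
school of medicine
corresponding author
conflict of interest
supplementary table
supplementary figure
received in revised form
accepted for publication
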