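Introduction

O-GlcNAcylation is a dynamic post-translational modification (PTM) of
nuclear and cytoplasmic proteins. Here we investigated the modification
of tau in human neurons.

Results

Immunoblotting showed that OGT (EC 2.4.1.255) modifies tau. We detected
O-GlcNAcylation of tau at Ser400 by mass spectrometry in human neurons.
Phosphorylation at Thr404 decreased upon OGT overexpression.

Discussion

These results demonstrate that tau O-GlcNAcylation at Ser400 antagonizes
phosphorylation in neurons.

References

1. A very long list of citations [removed].
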