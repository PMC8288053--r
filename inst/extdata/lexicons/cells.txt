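# word list: cell lines and cell types
hela
hek293
hek293t
cos7
nih3t3
cho
jurkat
pc12
sy5y
neuron
neurons
astrocyte
astrocytes
fibroblast
fibroblasts
hepatocyte
hepatocytes
lymphocyte
lymphocytes
macrophage
macrophages
cardiomyocyte
cardiomyocytes
myotube
islet
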