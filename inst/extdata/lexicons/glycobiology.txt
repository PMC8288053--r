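# word list: glycobiology vocabulary
glycosylation
glycan
glycans
glycoprotein
glycoproteins
glycosyltransferase
glycosidase
hexosamine
udpglcnac
sugar
carbohydrate
lectin
wga
sialic
galactose
glucosamine
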