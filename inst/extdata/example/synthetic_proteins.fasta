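>SYN0001 synthetic test protein 1
MSTAVLKRPSTGSKTLSAYR
>SYN0002 synthetic test protein 2
MKRPAKASRTSTPVSGTK
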