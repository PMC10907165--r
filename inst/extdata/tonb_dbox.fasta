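>TonB_Ec/43-54 E. coli TonB D-box peptide used for binding assays
QPISVTMVTPAD
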