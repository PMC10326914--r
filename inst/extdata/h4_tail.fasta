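>h4_tail_4_17 histone H4 peptide 4-17 benchmark region
GKGGKGLGKGGAKR
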