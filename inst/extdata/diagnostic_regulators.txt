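METTL16
RBM15B
KIAA1429
CBLL1
ALKBH5
ALKBH1
YTHDC2
YTHDF3
IGF2BP1
IGF2BP2
IGF2BP3
FMR1
LRPPRC
ELAVL1
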