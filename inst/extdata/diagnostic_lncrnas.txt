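ZNF582-AS1
ZNF503-AS2
UBL7-AS1
TTTY5
PRKAG2-AS1
LINC01007
LINC00424
ADARB2-AS1
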