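# demonstration disease gene set
APOE
APP
PSEN1
PSEN2
CLU
SORL1
PICALM
CR1
BACE1
NCSTN
TREM2
TYROBP
CD33
ABCA7
MISSING1
MISSING2
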