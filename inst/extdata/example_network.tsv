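# synthetic demonstration interaction network (not real interactions)
geneA	geneB
APOE	APP
APOE	PSEN1
APOE	CLU
APOE	SORL1
APP	PSEN1
APP	PSEN2
APP	BACE1
PSEN1	PSEN2
PSEN1	NCSTN
CLU	PICALM
CLU	CR1
SORL1	PICALM
BACE1	NCSTN
TREM2	TYROBP
TREM2	CD33
TYROBP	CD33
ABCA7	CD33
MAPT	GRN
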