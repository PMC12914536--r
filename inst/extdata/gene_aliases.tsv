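alias	canonical
TMEM173	STING1
MB21D1	CGAS
FIGF	VEGFD
PIGF	PGF
VEGFR2	KDR
VEGFR1	FLT1
CD31	PECAM1
TIE2	TEK
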