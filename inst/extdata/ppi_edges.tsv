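from	to
PRKCH	RELA
RELA	NFKBIA
RELA	NFKB1
NFKBIA	NFKB1
PRKCD	RELA
PRKCD	EGFR
EGFR	PLCG2
PLCG2	PRKCH
CLU	APOE
APOE	EGFR
PKN2	PRKCH
PRKCH	PRKCH
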