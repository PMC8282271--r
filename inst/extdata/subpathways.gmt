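nPKC_family	novel protein kinase C paralogs	PRKCD	PRKCH	PRKD3	PKN2
NFKB_complex	NF-kB transcription factor complex	NFKBIA	NFKB1	RELA
PLC_family	phospholipase C paralogs	PLCB1	PLCG2	PLCG1	PLCB4
CaMK_signaling	calcium/calmodulin-dependent kinases	CAMK2A	CAMK2B	CAMK4
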