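##fileformat=VCFv4.2
##source=centiskat
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=REGION,Number=1,Type=String,Description="Genomic region class">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##SAMPLE=<ID=case_0001,Status=case>
##SAMPLE=<ID=ctrl_0001,Status=control>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	case_0001	ctrl_0001
chr14	35874065	.	G	A	.	PASS	GENE=NFKBIA;REGION=upstream	GT	0/1	0/0
chr14	35874523	rs2233407	C	T	.	PASS	GENE=NFKBIA;REGION=upstream	GT	1/1	./.
chr14	61995673	rs2463117	T	C	.	PASS	GENE=PRKCH;REGION=intronic	GT	0/0	0/1
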