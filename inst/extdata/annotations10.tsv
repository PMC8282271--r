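variant	regulome_score	tf_or_dhs_overlap	ago_evidence_count	coding_effect
chr1:100:A:G	3a	TRUE	0	none
chr1:200:C:T	4	TRUE	0	none
chr1:300:G:A	6	TRUE	0	none
chr1:400:T:C	5	FALSE	0	none
chr1:500:A:C	7	FALSE	2	none
chr1:600:C:G	2b	TRUE	0	none
chr1:700:G:T	1a	FALSE	0	nonsynonymous
chr1:800:T:A	7	FALSE	1	none
chr1:900:A:T	5	TRUE	0	synonymous
chr1:1000:C:A	6	FALSE	0	none
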