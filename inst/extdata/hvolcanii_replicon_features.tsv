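replicon	size_bp	gc_percent	rrna_operons	trna	cds	is_ish51	is_is4	is_other	is_total	percent_coding	mean_pi
chromosome	2847757	66.6	2	51	2949	16	8	12	36	86.6	5.11
pHV4	635786	61.7	0	0	638	22	15	11	48	82.9	5.36
pHV3	437906	65.5	0	0	381	1	1	0	2	85.5	5.07
pHV1	85092	55.5	0	0	89	6	6	4	16	80.8	5.72
pHV2	6359	56	0	0	6	0	0	0	0	79.5	5.94
total	4012900	65	2	51	4063	45	30	27	102	NA	5.16
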