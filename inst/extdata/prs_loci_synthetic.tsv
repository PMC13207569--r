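rsid	chrom	pos	effect_allele	other_allele	beta
snpA01	1	101000	A	G	0.182
snpA02	1	202000	C	T	0.095
snpA03	2	303000	G	A	0.210
snpA04	2	404000	T	C	0.064
snpA05	3	505000	A	C	0.157
snpA06	3	606000	G	T	0.340
snpA07	4	707000	C	G	0.118
snpA08	5	808000	T	A	0.073
snpA09	5	909000	A	G	0.265
snpA10	6	1010000	C	T	0.142
snpA11	7	1111000	G	A	0.089
snpA12	8	1212000	T	C	0.198
snpA13	9	1313000	A	T	0.310
snpA14	10	1414000	C	A	0.125
snpA15	11	1515000	G	C	0.176
snpA16	12	1616000	T	G	0.052
snpA17	13	1717000	A	C	0.228
snpA18	14	1818000	G	T	0.104
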