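gene	column	allele_count	ac_check	freq_pct	freq_check	prevalence	prev_check	carrier	carrier_check
NPHS2	gnomAD	395/251020	denominator	0.157	exact	405696	exact	319	exact
NPHS2	gnomAD-SAS	29/30775	exact	0.094	exact	1131734	exact	532	exact
NPHS2	1KG	21/5008	exact	0.419	exact	56960	exact	120	exact
NPHS2	1KG-PJL	3/192	exact	1.560	deviation	4109	deviation	33	exact
NPHS2	gnomAD+1KG	416/256028	denominator	0.162	exact	381039	exact	309	exact
NPHS2	gnomAD-SAS+1KG-PJL	32/30967	exact	0.103	exact	942596	exact	486	exact
LAMB2	gnomAD	72/246450	denominator	0.029	exact	11890606	exact	1725	exact
LAMB2	gnomAD-SAS	40/30768	denominator	0.130	deviation	591716	deviation	385	deviation
LAMB2	1KG	2/5008	exact	0.039	exact	6574622	exact	1283	exact
LAMB2	1KG-PJL	1/192	exact	0.520	exact	36982	exact	97	exact
LAMB2	gnomAD+1KG	74/251458	denominator	0.029	exact	11890606	exact	1725	exact
LAMB2	gnomAD-SAS+1KG-PJL	41/30960	denominator	0.132	exact	573921	exact	379	exact
NPHS1	gnomAD	100/248788	denominator	0.040	exact	6250000	exact	1251	exact
NPHS1	gnomAD-SAS	53/30772	denominator	0.172	exact	338021	exact	291	exact
NPHS1	1KG	0/5008	exact	0.000	exact	-	exact	-	exact
NPHS1	1KG-PJL	0/192	exact	0.000	exact	-	exact	-	exact
NPHS1	gnomAD+1KG	100/253796	denominator	0.039	exact	6574622	exact	1283	exact
NPHS1	gnomAD-SAS+1KG-PJL	53/30964	denominator	0.171	exact	341986	exact	293	exact
COMBINED	gnomAD	567/248753	denominator	0.227	deviation	194065	deviation	221	deviation
COMBINED	gnomAD-SAS	127/30771	deviation	0.412	deviation	58912	deviation	122	deviation
COMBINED	1KG	23/5008	exact	0.459	exact	47465	exact	109	exact
COMBINED	1KG-PJL	4/192	exact	2.080	deviation	2311	deviation	25	exact
COMBINED	gnomAD+1KG	590/253761	denominator	0.230	deviation	189036	deviation	218	deviation
COMBINED	gnomAD-SAS+1KG-PJL	-	deviation	0.420	deviation	56689	deviation	120	deviation
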