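gene	column	allele_count	ac_check	freq_pct	freq_check	prevalence	prev_check	carrier	carrier_check
NPHS2	gnomAD	380/256102	exact	0.148	exact	456538	exact	338	exact
NPHS2	gnomAD-SAS	15/30772	exact	0.048	exact	4340278	exact	1042	exact
NPHS2	1KG	20/5008	exact	0.399	exact	62814	exact	126	exact
NPHS2	1KG-PJL	3/192	exact	1.560	deviation	4109	deviation	33	exact
NPHS2	gnomAD+1KG	400/261110	exact	0.153	exact	427186	exact	327	exact
NPHS2	gnomAD-SAS+1KG-PJL	18/30964	exact	0.058	exact	2972652	exact	863	exact
LAMB2	gnomAD	13/244165	exact	0.005	exact	400000000	exact	10001	exact
LAMB2	gnomAD-SAS	7/30760	exact	0.022	exact	20661157	exact	2273	exact
LAMB2	1KG	0/5008	exact	0.000	exact	-	exact	-	exact
LAMB2	1KG-PJL	0/192	exact	0.000	exact	-	exact	-	exact
LAMB2	gnomAD+1KG	13/249173	exact	0.005	exact	400000000	exact	10001	exact
LAMB2	gnomAD-SAS+1KG-PJL	7/30952	exact	0.022	exact	20661157	exact	2273	exact
NPHS1	gnomAD	58/251247	denominator	0.023	exact	18903592	exact	2174	exact
NPHS1	gnomAD-SAS	31/30772	exact	0.100	exact	1000000	exact	501	exact
NPHS1	1KG	0/5008	exact	0.000	exact	-	exact	-	exact
NPHS1	1KG-PJL	0/192	exact	0.000	exact	-	exact	-	exact
NPHS1	gnomAD+1KG	58/256255	denominator	0.022	exact	20661157	exact	2273	exact
NPHS1	gnomAD-SAS+1KG-PJL	31/30964	exact	0.100	exact	1000000	exact	501	exact
COMBINED	gnomAD	451/250505	denominator	0.180	exact	308642	exact	278	exact
COMBINED	gnomAD-SAS	53/30768	exact	0.172	exact	338021	exact	291	exact
COMBINED	1KG	20/5008	exact	0.399	exact	62814	exact	126	exact
COMBINED	1KG-PJL	3/192	exact	1.560	deviation	4109	deviation	33	exact
COMBINED	gnomAD+1KG	471/255513	denominator	0.184	exact	295369	exact	272	exact
COMBINED	gnomAD-SAS+1KG-PJL	56/30960	exact	0.180	exact	308642	exact	278	exact
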