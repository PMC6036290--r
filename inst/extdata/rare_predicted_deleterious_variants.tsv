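gene	chrom	pos	rsid	ref	alt	consequence	GNOMAD_ALL	GNOMAD_SAS	KG_ALL	KG_PJL	sift	pph2	ma	fathmm	condel	condel_label
LAMB2	3	49158944	rs760355583	G	A	p.Gln1728Ter	1/246228	1/30782	-	-	-	-	-	-	-	-
LAMB2	3	49166461	rs759042337	G	A	p.Arg575Ter	7/241974	4/30762	-	-	-	-	-	-	-	-
LAMB2	3	49168473	rs769460144	A	T	p.Tyr275Ter	1/244402	1/30750	-	-	-	-	-	-	-	-
LAMB2	3	49167271	rs780041521	C	T	c.1405+1G>A	4/244056	1/30746	-	-	-	-	-	-	-	-
NPHS2	1	179520496	rs763818901	G	A	p.Arg322Ter	1/245804	1/30782	-	-	-	-	-	-	-	-
NPHS2	1	179526186	rs748812981	C	A	p.Arg238Ser	4/276486	1/30736	-	-	0	0.998	3.545	-4.37	0.68850199	D
NPHS2	1	179526191	rs146906190	C	G	p.Glu237Gln	205/276570	4/30748	1/5008	0/192	0	0.998	3.545	-4.37	0.68850199	D
NPHS2	1	179526362	rs74315347	C	T	p.Val180Met	3/245560	1/30778	-	-	0.02	0.577	1.005	-6.26	0.605115534	D
NPHS2	1	179530462	rs74315342	C	T	p.Arg138Gln	159/277072	2/30782	-	-	0.02	0.999	2.28	-6.29	0.641951573	D
NPHS2	1	179533825	rs771320565	CT	C	p.Lys126ArgfsTer9	1/246163	1/30781	-	-	-	-	-	-	-	-
NPHS2	1	179520587	rs776016942	C	T	c.874-1G>A	1/245424	1/30778	-	-	-	-	-	-	-	-
NPHS2	1	179520493	rs571452152	A	G	p.Tyr323His	1/245830	0/30780	1/5008	1/192	0.01	0.574	2.945	-6.26	0.671811197	D
NPHS2	1	179526301	rs542500942	G	A	p.Ala200Val	5/246006	4/30780	1/5008	1/192	0.03	0.449	1.47	-3.69	0.554213306	D
NPHS2	1	179544873	rs545872093	G	C	p.Pro43Ala	-	-	17/5008	1/192	0.86	0	-0.205	-5.84	0.529596199	D
NPHS1	19	36330221	rs762184939	G	C	p.Tyr1009Ter	2/246268	2/30780	-	-	-	-	-	-	-	-
NPHS1	19	36339690	rs386833861	G	T	p.Pro340His	3/246204	3/30782	-	-	0.04	1	1.935	-4.45	0.57449583	D
NPHS1	19	36339995	rs753476209	G	A	p.Arg299Cys	2/240156	1/30768	-	-	0.02	0.912	1.77	-1	0.549329816	D
NPHS1	19	36340176	rs749341977	G	A	p.Arg268Ter	6/275332	0/30772	-	-	-	-	-	-	-	-
NPHS1	19	36341889	rs386833945	G	A	p.Pro167Leu	1/246044	1/30780	-	-	1	1	2.005	-3.06	0.561752557	D
NPHS1	19	36339610	rs386833865	G	A	p.Arg367Cys	10/246176	4/30782	-	-	0.01	0.964	1.845	-1.07	0.547062581	D
NPHS1	19	36342241	rs386833934	G	A	p.Ala107Val	3/244336	2/30718	-	-	0.01	0.98	3.22	0.59	0.631325147	D
NPHS1	19	36330189	rs749003854	C	A	p.Gly1020Val	6/246268	6/30782	-	-	0	1	3.755	-0.89	0.773421163	D
NPHS1	19	36321958	rs267606919	G	A	p.Arg1160Ter	25/246216	12/30782	-	-	-	-	-	-	-	-
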