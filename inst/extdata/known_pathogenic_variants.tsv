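gene	chrom	pos	rsid	ref	alt	consequence	GNOMAD_ALL	GNOMAD_SAS	KG_ALL	KG_PJL	sift	pph2	ma	fathmm	condel	condel_label
NPHS2	1	179520493	rs571452152	A	G	p.Tyr255His	1/245830	0/30780	1/5008	-	0.01	0.574	2.95	-6.26	0.6718112	D
NPHS2	1	179520354	rs768932711	G	A	p.Pro369Leu	2/245844	2/30778	-	-	0.15	0.001	0	-6	0.5486173	D
NPHS2	1	179520418	rs754243843	T	G	p.Asn348His	1/245938	1/30782	-	-	0.04	0.45	1.46	-6.3	0.621615	D
NPHS2	1	179520429	rs751105124	A	G	p.Phe344Ser	2/245958	2/30780	-	-	0	0.007	1.15	-6.15	0.6076879	D
NPHS2	1	179521804	rs770495227	C	A	p.Arg269Ser	1/245354	1/30744	-	-	0.21	0.029	0.56	-6.24	0.5838985	D
NPHS2	1	179526298	rs771256385	G	T	p.Ser201Tyr	1/246000	1/30782	-	-	0.02	0.044	0.8	-6.4	0.6003373	D
NPHS2	1	179526308	rs765185151	C	G	p.Glu198Gln	1/245982	1/30778	-	-	0.35	0.47	0.75	-3.54	0.5275746	D
NPHS2	1	179533863	rs779163992	T	G	p.Ile114Leu	1/246156	1/30782	-	-	0.26	0.025	1.21	-6.25	0.6123593	D
NPHS2	1	179533901	rs777738678	C	G	p.Cys101Ser	1/246108	1/30782	-	-	0	0.131	2.52	-5.92	0.6424912	D
NPHS2	1	179526338	rs757665750	C	A	p.Glu188Ter	2/245860	2/30780	-	-	-	-	-	-	-	-
NPHS2	1	179530438	rs778201387	CT	C	p.Arg146GlufsTer35	1/246138	1/30782	-	-	-	-	-	-	-	-
NPHS2	1	179533920	rs759842258	A	AT	p.Ser95IlefsTer8	1/246070	1/30770	-	-	-	-	-	-	-	-
LAMB2	3	49158675	rs769627057	T	C	p.Tyr1794Cys	1/246080	1/30780	-	-	0	0.998	2.69	0.53	0.57388975	D
LAMB2	3	49159680	rs779155013	A	G	p.Leu1566Pro	1/245622	1/30772	-	-	0	0.963	2.59	0.92	0.53606262	D
LAMB2	3	49161398	rs760892618	C	T	p.Cys1187Tyr	1/244248	1/30774	-	-	0	0.999	4.61	1.39	0.71407755	D
LAMB2	3	49161433	rs750381148	C	A	p.Gln1175His	3/244722	3/30773	-	-	0.04	0.999	2.08	-0.03	0.52880462	D
LAMB2	3	49161479	rs559556131	C	T	p.Gly1160Asp	3/244552	3/30780	-	-	0	1	4.67	-1.34	0.85034712	D
LAMB2	3	49162278	rs766539657	T	G	p.Ser989Arg	1/246238	1/30782	-	-	0	0.241	2.88	0.06	0.61882555	D
LAMB2	3	49162280	rs754732425	C	T	p.Cys988Tyr	3/246234	2/30782	-	-	0	0.999	4.6	-3.67	0.77695588	D
LAMB2	3	49162299	rs530751136	G	A	p.Arg982Trp	2/246208	0/30782	1/5008	1/192	0.02	0.861	2.31	0.06	0.55138327	D
LAMB2	3	49162302	rs778680962	C	T	p.Gly981Ser	1/246222	1/30782	-	-	0.06	1	2.14	0.16	0.5256399	D
LAMB2	3	49162334	rs763062098	G	A	p.Pro970Leu	1/246106	1/30782	-	-	0.14	0.999	2.51	-0.05	0.58191315	D
LAMB2	3	49162504	rs749808119	G	A	p.Ala940Val	2/243584	1/30766	-	-	0.03	0.999	3.59	-0.14	0.70961854	D
LAMB2	3	49162716	rs375392013	C	T	p.Arg897His	2/240634	1/30782	-	-	0.21	0.999	2.16	-0.02	0.53696553	D
LAMB2	3	49162762	rs751697643	G	A	p.His882Tyr	1/246028	1/30780	-	-	0.02	0.664	3.89	-0.15	0.74173607	D
LAMB2	3	49162811	rs771584138	C	G	p.Gln865His	1/245372	1/30780	-	-	0.12	0.894	2.16	0	0.5357451	D
LAMB2	3	49163579	rs764955129	G	A	p.Pro722Leu	1/244568	1/30770	-	-	0.02	0.248	2.69	0.7	0.56367037	D
LAMB2	3	49166738	rs751844883	C	T	p.Ser513Asn	2/245150	2/30758	-	-	0.05	0.911	2.26	0.07	0.54547393	D
LAMB2	3	49168184	rs747053168	T	C	p.His342Arg	1/246178	1/30782	-	-	0.04	0.63	2.19	0.03	0.53820621	D
LAMB2	3	49168388	rs775204900	C	T	p.Gly304Ser	5/246088	1/30782	-	-	0.04	1	2.92	-0.2	0.63898086	D
LAMB2	3	49168417	rs536441871	G	T	p.Pro294His	1/245872	1/30776	1/5008	0/192	0.05	0.982	3.5	0.06	0.68772865	D
LAMB2	3	49168439	rs780152505	C	T	p.Gly287Arg	3/276512	1/30772	-	-	0	1	3.78	-0.3	0.738678	D
LAMB2	3	49168498	rs772368832	C	T	p.Arg267Gln	7/273782	1/30718	-	-	0.52	0.591	0.98	-0.96	0.52262762	D
LAMB2	3	49169033	rs147986864	G	A	p.Arg195Trp	9/275688	1/30768	-	-	0	0.979	2.55	-1.13	0.63595261	D
LAMB2	3	49169603	rs758877377	G	C	p.Ile135Met	2/246268	2/30782	-	-	0.01	0.961	3.19	-1.3	0.70191895	D
LAMB2	3	49169732	rs752886136	C	T	p.Arg119Gln	1/246262	1/30782	-	-	0.59	0.767	3.01	-0.96	0.69118365	D
LAMB2	3	49169807	rs767544919	C	T	p.Arg94Gln	3/246272	2/30782	-	-	0.18	0.999	2.06	-0.96	0.58205729	D
LAMB2	3	49169958	rs776819202	C	T	p.Gly72Asp	1/245660	1/30782	-	-	0.11	0.306	3.06	-0.96	0.69687401	D
NPHS1	19	36321826	rs777436326	G	C	p.Pro1172Ala	1/246246	0/30782	-	-	0.32	0.563	0.9	-2.97	0.52476152	D
NPHS1	19	36330157	rs757169332	G	A	p.Leu1031Phe	1/246246	1/30782	-	-	0.01	0.34	1.59	-0.85	0.55029744	D
NPHS1	19	36330288	rs746380730	T	C	p.Tyr987Cys	1/246264	1/30782	-	-	0.04	0.982	2.76	0.43	0.58656495	D
NPHS1	19	36333170	rs748705495	A	C	p.Val840Gly	1/244238	1/30756	-	-	0	0.975	1.55	-0.91	0.54873772	D
NPHS1	19	36334444	rs750854389	C	A	p.Gly755Val	1/246270	1/30782	-	-	0.07	0.286	1.94	-1.27	0.54028481	D
NPHS1	19	36336347	rs762869410	C	T	p.Gly618Asp	1/245808	1/30778	-	-	0.04	0.599	2.22	-1.08	0.59841388	D
NPHS1	19	36336356	rs751046394	C	A	p.Arg615Leu	2/245746	2/30782	-	-	0.19	0.192	1.25	-0.99	0.53620728	D
NPHS1	19	36336408	rs758946523	G	A	p.Pro598Ser	1/234914	1/30781	-	-	0.64	0.551	1.12	-1.02	0.53008798	D
NPHS1	19	36336592	rs764351102	G	A	p.Ser579Tyr	1/245252	1/30707	-	-	0.09	0.798	2.34	-1.2	0.60973898	D
NPHS1	19	36339005	rs749319334	G	A	p.Arg460Trp	6/276520	1/30766	-	-	0.19	0.011	1.74	-1.04	0.54867583	D
NPHS1	19	36339010	rs768870360	C	G	p.Gly458Ala	1/245546	1/30764	-	-	0	0.999	2.11	-2.79	0.56791611	D
NPHS1	19	36339250	rs199735886	C	T	p.Arg407Gln	16/246214	2/30782	-	-	0.23	0.271	1.36	-0.96	0.54186854	D
NPHS1	19	36339691	rs746481345	G	A	p.Pro340Ser	1/246208	1/30782	-	-	0.1	1	1.94	-4.43	0.57397387	D
NPHS1	19	36339983	rs761786407	C	T	p.Val303Met	1/240840	1/30778	-	-	0.08	0.571	1	-0.91	0.52460566	D
NPHS1	19	36340149	rs752311438	G	T	p.Gln277Lys	1/245308	1/30780	-	-	1	0.88	1.05	-1.04	0.52596441	D
NPHS1	19	36340525	rs779764581	C	A	p.Gln213His	2/246176	2/30782	-	-	0.05	0.571	1.1	-2.08	0.52665949	D
NPHS1	19	36341334	rs779291027	T	C	p.Ile180Met	3/246262	3/30782	-	-	0.15	0.609	1.1	-0.9	0.52979925	D
NPHS1	19	36342391	rs761152159	G	C	p.Pro81Arg	1/239854	1/30736	-	-	0.01	0.996	2.47	0.88	0.52561198	D
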