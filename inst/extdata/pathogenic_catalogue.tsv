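chrom	pos	ref	alt	rsid	source_id	significance
1	179520493	A	G	rs571452152	rs571452152	pathogenic
1	179520354	G	A	rs768932711	rs768932711	pathogenic
1	179520418	T	G	rs754243843	rs754243843	pathogenic
1	179520429	A	G	rs751105124	rs751105124	pathogenic
1	179521804	C	A	rs770495227	rs770495227	pathogenic
1	179526298	G	T	rs771256385	rs771256385	pathogenic
1	179526308	C	G	rs765185151	rs765185151	pathogenic
1	179533863	T	G	rs779163992	rs779163992	pathogenic
1	179533901	C	G	rs777738678	rs777738678	pathogenic
1	179526338	C	A	rs757665750	rs757665750	pathogenic
1	179530438	CT	C	rs778201387	rs778201387	pathogenic
1	179533920	A	AT	rs759842258	rs759842258	pathogenic
3	49158675	T	C	rs769627057	rs769627057	pathogenic
3	49159680	A	G	rs779155013	rs779155013	pathogenic
3	49161398	C	T	rs760892618	rs760892618	pathogenic
3	49161433	C	A	rs750381148	rs750381148	pathogenic
3	49161479	C	T	rs559556131	rs559556131	pathogenic
3	49162278	T	G	rs766539657	rs766539657	pathogenic
3	49162280	C	T	rs754732425	rs754732425	pathogenic
3	49162299	G	A	rs530751136	rs530751136	pathogenic
3	49162302	C	T	rs778680962	rs778680962	pathogenic
3	49162334	G	A	rs763062098	rs763062098	pathogenic
3	49162504	G	A	rs749808119	rs749808119	pathogenic
3	49162716	C	T	rs375392013	rs375392013	pathogenic
3	49162762	G	A	rs751697643	rs751697643	pathogenic
3	49162811	C	G	rs771584138	rs771584138	pathogenic
3	49163579	G	A	rs764955129	rs764955129	pathogenic
3	49166738	C	T	rs751844883	rs751844883	pathogenic
3	49168184	T	C	rs747053168	rs747053168	pathogenic
3	49168388	C	T	rs775204900	rs775204900	pathogenic
3	49168417	G	T	rs536441871	rs536441871	pathogenic
3	49168439	C	T	rs780152505	rs780152505	pathogenic
3	49168498	C	T	rs772368832	rs772368832	pathogenic
3	49169033	G	A	rs147986864	rs147986864	pathogenic
3	49169603	G	C	rs758877377	rs758877377	pathogenic
3	49169732	C	T	rs752886136	rs752886136	pathogenic
3	49169807	C	T	rs767544919	rs767544919	pathogenic
3	49169958	C	T	rs776819202	rs776819202	pathogenic
19	36321826	G	C	rs777436326	rs777436326	pathogenic
19	36330157	G	A	rs757169332	rs757169332	pathogenic
19	36330288	T	C	rs746380730	rs746380730	pathogenic
19	36333170	A	C	rs748705495	rs748705495	pathogenic
19	36334444	C	A	rs750854389	rs750854389	pathogenic
19	36336347	C	T	rs762869410	rs762869410	pathogenic
19	36336356	C	A	rs751046394	rs751046394	pathogenic
19	36336408	G	A	rs758946523	rs758946523	pathogenic
19	36336592	G	A	rs764351102	rs764351102	pathogenic
19	36339005	G	A	rs749319334	rs749319334	pathogenic
19	36339010	C	G	rs768870360	rs768870360	pathogenic
19	36339250	C	T	rs199735886	rs199735886	pathogenic
19	36339691	G	A	rs746481345	rs746481345	pathogenic
19	36339983	C	T	rs761786407	rs761786407	pathogenic
19	36340149	G	T	rs752311438	rs752311438	pathogenic
19	36340525	C	A	rs779764581	rs779764581	pathogenic
19	36341334	T	C	rs779291027	rs779291027	pathogenic
19	36342391	G	C	rs761152159	rs761152159	pathogenic
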