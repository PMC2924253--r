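probe_id	gene	location	coef	exp_coef	se_coef	z	p	q
cg01172656	NRBF2	10:64563126	0.631	1.880	0.136	4.653	3.266e-06	0.031
cg18346038	PIGU	20:32728489	0.624	1.867	0.136	4.603	4.164e-06	0.031
cg00117172	RUNX3	1:25128425	0.682	1.977	0.150	4.548	5.427e-06	0.031
cg02068676	COBRA1	9:139269304	0.662	1.938	0.149	4.447	8.703e-06	0.037
cg00025138	MAP3K9	14:70345670	0.543	1.721	0.125	4.335	1.457e-05	0.046
cg03221776	MFSD3	8:145704779	0.520	1.682	0.121	4.308	1.644e-05	0.046
cg12181621	HIST1H3I	6:27948047	0.558	1.748	0.132	4.216	2.486e-05	0.048
cg03752885	DAPK3	19:3920736	0.492	1.636	0.118	4.189	2.798e-05	0.048
cg12688215	KTI12	1:52271816	0.446	1.563	0.107	4.175	2.976e-05	0.048
cg07341907	UNC13B	9:35151971	0.606	1.833	0.145	4.169	3.056e-05	0.048
cg26850145	ZBTB5	9:37455023	-0.485	0.616	0.117	-4.142	3.441e-05	0.048
cg21312090	TRPS1	8:116750901	0.441	1.555	0.107	4.135	3.543e-05	0.048
cg23266266	DCUN1D4	4:52403466	0.560	1.751	0.136	4.117	3.847e-05	0.048
cg04466870	SFXN4	10:120915170	0.477	1.611	0.116	4.102	4.092e-05	0.048
cg16898420	PPAPR3	9:102830899	-0.711	0.491	0.175	-4.066	4.786e-05	0.048
cg17260725	CCNB2	15:57184580	0.523	1.687	0.129	4.0596	4.915e-05	0.048
cg17428423	DOC2A	16:29929633	-0.728	0.483	0.180	-4.053	5.049e-05	0.048
cg18731014	ZNF639	3:180524284	0.556	1.744	0.137	4.050	5.122e-05	0.048
cg21830413	VPS26	10:70554257	0.472	1.604	0.117	4.036	5.430e-05	0.048
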