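# synthetic example peak table (33 methyl probes: 18 core, 7 P1, 8 P2)
residue	residue_type	wH_ppm	wC_ppm	intensity	noise_floor	domain	flags
60	Met-e	1.847	16.992	0.8294	0.05	core-N	
63	Met-e	1.882	14.347	0.7011	0.05	core-N	
66	Ile-d1	0.236	12.487	0.7215	0.05	core-N	
70	Ile-d1	0.681	11.045	1.2428	0.05	core-N	
87	Met-e	1.845	17.259	1.2913	0.05	core-N	
101	Ile-d1	0.593	11.852	1.1492	0.05	core-N	
147	Ile-d1	1.008	14.246	0.7809	0.05	core-N	
150	Ile-d1	0.811	12.351	1.223	0.05	core-N	
180	Ile-d1	0.497	14.983	1.2563	0.05	core-N	
184	Ile-d1	0.474	11.647	1.1025	0.05	core-N	
213	Ile-d1	0.597	10.648	1.0328	0.05	core-N	
220	Met-e	1.661	15.956	1.1899	0.05	P1	
224	Met-e	1.94	16.431	0.8305	0.05	P1	
231	Ile-d1	0.753	11.186	0.8321	0.05	P1	
245	Met-e	1.846	17.283	0.9307	0.05	P1	
256	Met-e	1.97	15.761	1.1329	0.05	P1	
261	Ile-d1	0.943	13.592	1.263	0.05	P1	
263	Ile-d1	0.756	12.228	0.8607	0.05	P1	
267	Met-e	2.032	16.147	1.2548	0.05	P2	
268	Ile-d1	0.652	10.833	1.0906	0.05	P2	
269	Ile-d1	0.561	16.297	0.8499	0.05	P2	
293	Ile-d1	0.807	12.173	0.9363	0.05	P2	
294	Ile-d1	0.758	12.2	0.9178	0.05	P2	
313	Ile-d1	0.575	13.687	1.0833	0.05	P2	
324	Ile-d1	0.703	11.982	0.7618	0.05	P2	
333	Ile-d1	0.602	12.746	1.1183	0.05	P2	
340	Ile-d1	1.009	13.152	1.0428	0.05	core-C	
352	Ile-d1	0.613	14.192	0.8491	0.05	core-C	
366	Met-e	1.832	16.835	1.2241	0.05	core-C	
379	Met-e	2.103	15.539	0.7679	0.05	core-C	
400	Ile-d1	0.921	11.826	1.1513	0.05	core-C	
405	Met-e	1.932	15.404	1.1224	0.05	core-C	
421	Ile-d1	0.797	10.003	0.9433	0.05	core-C	
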