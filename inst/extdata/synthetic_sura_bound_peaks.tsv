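# synthetic example peak table, client-bound state
residue	residue_type	wH_ppm	wC_ppm	intensity	noise_floor	domain	flags
60	Met-e	1.847	16.992	0.2458	0.05	core-N	
63	Met-e	1.882	14.347	0.3785	0.05	core-N	
66	Ile-d1	0.256	12.607	0.2679	0.05	core-N	
70	Ile-d1	0.701	11.165	0.6489	0.05	core-N	
87	Met-e	1.845	17.259	0.5057	0.05	core-N	
101	Ile-d1	0.593	11.852	0.6337	0.05	core-N	
147	Ile-d1	1.008	14.246	0.2251	0.05	core-N	
150	Ile-d1	0.811	12.351	0.7028	0.05	core-N	
180	Ile-d1	0.497	14.983	0.5863	0.05	core-N	
184	Ile-d1	0.474	11.647	0.4283	0.05	core-N	
213	Ile-d1	0.617	10.768	0.4847	0.05	core-N	
220	Met-e	1.661	15.956	0.5057	0.05	P1	
224	Met-e	1.94	16.431	0.4331	0.05	P1	
231	Ile-d1	0.753	11.186	0.4823	0.05	P1	
245	Met-e	1.846	17.283	0.01	0.05	P1	broadened_below_noise
256	Met-e	1.97	15.761	0.5302	0.05	P1	
261	Ile-d1	0.943	13.592	0.785	0.05	P1	
263	Ile-d1	0.756	12.228	0.5198	0.05	P1	
267	Met-e	2.032	16.147	0.9479	0.05	P2	
268	Ile-d1	0.652	10.833	0.9925	0.05	P2	
269	Ile-d1	0.561	16.297	0.672	0.05	P2	
293	Ile-d1	0.807	12.173	0.7105	0.05	P2	
294	Ile-d1	0.758	12.2	0.7357	0.05	P2	
313	Ile-d1	0.575	13.687	0.8935	0.05	P2	
324	Ile-d1	0.703	11.982	0.6364	0.05	P2	
333	Ile-d1	0.602	12.746	1.0162	0.05	P2	
340	Ile-d1	1.009	13.152	0.4145	0.05	core-C	
352	Ile-d1	0.613	14.192	0.4615	0.05	core-C	
366	Met-e	1.832	16.835	0.4598	0.05	core-C	
379	Met-e	2.103	15.539	0.4235	0.05	core-C	
400	Ile-d1	0.921	11.826	0.4061	0.05	core-C	
405	Met-e	1.932	15.404	0.6481	0.05	core-C	
421	Ile-d1	0.797	10.003	0.5277	0.05	core-C	
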