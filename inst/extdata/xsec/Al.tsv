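# photon mass interaction coefficients, cm^2/g
# element Al  Z=13  A=26.98154 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	1093.74	1092.06	1.66433	0.0247014	1092.06
1.05257	956.763	955.088	1.64799	0.0267701	955.089
1.1079	836.632	834.973	1.63055	0.0289685	834.973
1.16614	731.318	729.675	1.61199	0.0312966	729.675
1.22745	639.028	637.402	1.59231	0.0337534	637.402
1.29198	558.181	556.573	1.57152	0.0363361	556.574
1.35989	487.384	485.796	1.54964	0.0390405	485.796
1.43138	425.188	423.619	1.5267	0.0418603	423.619
1.50663	370.791	369.243	1.50275	0.044788	369.243
1.55726	339.404	337.871	1.4868	0.0467296	337.871
1.56194	4096.86	4095.33	1.48533	0.0469078	4095.33
1.58583	4023.27	4021.75	1.47786	0.0478141	4021.75
1.6692	3658.01	3656.51	1.45209	0.0509279	3656.51
1.75695	3207.14	3205.66	1.42554	0.0541173	3205.66
1.84931	2811.06	2809.6	1.39828	0.0573696	2809.6
1.94653	2463.21	2461.78	1.37043	0.0606715	2461.78
2.04886	2158.88	2157.47	1.34207	0.0640095	2157.47
2.15656	1894.52	1893.14	1.31331	0.0673709	1893.14
2.26993	1660.97	1659.61	1.28423	0.0707436	1659.61
2.38926	1454.85	1453.52	1.25492	0.0741171	1453.52
2.51487	1273.14	1271.84	1.22545	0.0774822	1271.84
2.64707	1113.1	1111.83	1.19586	0.0808318	1111.83
2.78623	972.292	971.042	1.1662	0.0841607	971.042
2.9327	848.515	847.291	1.1365	0.0874654	847.292
3.08687	739.756	738.558	1.10676	0.0907442	738.559
3.24915	643.875	642.704	1.07699	0.0939968	642.705
3.41995	559.966	558.822	1.04717	0.0972239	558.822
3.59974	486.704	485.586	1.01729	0.100427	485.587
3.78897	422.777	421.686	0.987327	0.103609	421.687
3.98816	367.03	365.966	0.957252	0.106772	365.967
4.19782	318.447	317.41	0.927036	0.109919	317.411
4.41849	276.134	275.124	0.896649	0.113053	275.125
4.65077	239.305	238.323	0.866065	0.116175	238.324
4.89526	207.27	206.315	0.835262	0.119289	206.316
5.1526	179.421	178.494	0.804224	0.122394	178.495
5.42347	155.226	154.327	0.772953	0.12549	154.329
5.70858	134.219	133.349	0.741463	0.128574	133.351
6.00868	115.991	115.149	0.709792	0.131641	115.151
6.32456	100.184	99.3712	0.677997	0.134682	99.373
6.65703	86.4845	85.7007	0.646162	0.137689	85.7027
7.00699	74.6022	73.8471	0.614387	0.140648	73.8493
7.37535	64.3206	63.5943	0.582797	0.143545	63.5966
7.76307	55.4357	54.7378	0.551528	0.146365	54.7403
8.17117	47.7612	47.0914	0.520727	0.149091	47.094
8.60072	41.1352	40.493	0.490542	0.151707	40.4958
9.05286	35.4015	34.7862	0.461119	0.154198	34.7892
9.52877	30.4335	29.8444	0.432595	0.156548	29.8476
10.0297	26.159	25.5952	0.405091	0.158745	25.5986
10.5569	22.4824	21.9429	0.378707	0.16078	21.9465
11.1119	19.321	18.8048	0.35352	0.162646	18.8086
11.6961	16.6034	16.1095	0.329582	0.164337	16.1135
12.3109	14.2682	13.7954	0.306923	0.165853	13.7996
12.9581	12.2621	11.8093	0.285547	0.167195	11.8138
13.6393	10.5392	10.1054	0.265439	0.168364	10.1101
14.3563	9.06003	8.6441	0.246568	0.169366	8.64901
15.111	7.79043	7.39134	0.228891	0.170206	7.39649
15.9054	6.70101	6.31776	0.212356	0.170892	6.32317
16.7416	5.76643	5.39809	0.196907	0.171428	5.40375
17.6217	4.96487	4.61056	0.182486	0.171823	4.61649
18.548	4.27756	3.93644	0.169038	0.172083	3.94264
19.5231	3.68834	3.35962	0.156507	0.172215	3.36609
20.5494	3.1833	2.86624	0.144845	0.172223	2.873
21.6297	2.7505	2.44439	0.134004	0.172113	2.45144
22.7667	2.37967	2.08384	0.12394	0.171891	2.09119
23.9636	2.06197	1.77579	0.114613	0.171561	1.78346
25.2233	1.78982	1.51271	0.105984	0.171127	1.52069
26.5493	1.55673	1.28812	0.0980153	0.170594	1.29642
27.945	1.35696	1.09633	0.0906689	0.169965	1.10496
29.4141	1.18592	0.932763	0.0839083	0.169246	0.941741
30.9603	1.03947	0.793334	0.0776967	0.168439	0.802659
32.5879	0.914067	0.67452	0.0719978	0.16755	0.6842
34.3011	0.806663	0.573307	0.0667761	0.166581	0.583349
36.1042	0.714649	0.487116	0.0619967	0.165536	0.497528
38.0022	0.63579	0.413745	0.0576261	0.16442	0.424532
40	0.568173	0.351306	0.0536324	0.163235	0.362476
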