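# photon mass interaction coefficients, cm^2/g
# element Cu  Z=29  A=63.54600 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	10478.4	10474.7	3.72916	0.0107679	10474.7
1.05257	8995.86	8992.13	3.71184	0.0117542	8992.13
1.1079	8874.31	8870.6	3.69301	0.012822	8870.6
1.16614	7974.39	7970.7	3.67258	0.0139758	7970.7
1.22745	7064.37	7060.71	3.65046	0.0152203	7060.71
1.29198	6253.02	6249.38	3.62654	0.0165599	6249.38
1.35989	5530.21	5526.6	3.60073	0.017999	5526.6
1.43138	4886.04	4882.45	3.57294	0.0195415	4882.45
1.50663	4310.94	4307.37	3.54309	0.0211911	4307.37
1.58583	3800.75	3797.21	3.51109	0.0229511	3797.21
1.6692	3348.56	3345.06	3.47687	0.0248245	3345.06
1.75695	2947.99	2944.52	3.44036	0.0268136	2944.52
1.84931	2593.46	2590.03	3.40149	0.0289204	2590.03
1.94653	2279.93	2276.54	3.36022	0.0311466	2276.54
2.04886	2002.89	1999.54	3.31648	0.0334931	1999.54
2.15656	1758.28	1754.97	3.27025	0.0359608	1754.97
2.26993	1542.34	1539.08	3.22148	0.0385501	1539.08
2.38926	1351.97	1348.76	3.17013	0.0412611	1348.76
2.51487	1184.35	1181.19	3.11618	0.0440937	1181.19
2.64707	1036.87	1033.76	3.0596	0.0470476	1033.76
2.78623	907.198	904.148	3.00037	0.0501219	904.148
2.9327	793.272	790.28	2.93846	0.0533157	790.281
3.08687	693.018	690.087	2.87389	0.0566272	690.088
3.24915	605.009	602.142	2.80665	0.0600536	602.143
3.41995	527.971	525.171	2.73678	0.0635913	525.171
3.59974	460.568	457.836	2.66434	0.0672347	457.837
3.78897	401.574	398.914	2.58944	0.0709766	398.914
3.98816	349.878	347.291	2.5122	0.0748077	347.292
4.19782	304.753	302.241	2.43282	0.0787164	302.242
4.41849	265.38	262.945	2.35151	0.0826887	262.946
4.65077	231.036	228.68	2.26855	0.0867086	228.681
4.89526	201.049	198.774	2.18425	0.0907582	198.775
5.1526	174.896	172.702	2.09896	0.094818	172.703
5.42347	152.115	150.004	2.01305	0.0988676	150.005
5.70858	132.278	130.249	1.92691	0.102886	130.25
6.00868	115.008	113.061	1.84092	0.106853	113.062
6.32456	99.9773	98.1111	1.75548	0.110747	98.1127
6.65703	86.8977	85.1122	1.67097	0.114549	85.1139
7.00699	75.5187	73.8128	1.58774	0.118241	73.8147
7.37535	65.6216	63.9936	1.50614	0.121807	63.9957
7.76307	57.0151	55.4634	1.42647	0.125231	55.4656
8.17117	49.5326	48.0551	1.349	0.1285	48.0575
8.60072	43.0285	41.623	1.27399	0.131603	41.6255
8.96543	38.3794	37.0303	1.21514	0.13399	37.0329
8.99237	297.958	296.613	1.21095	0.134157	198.476
9.05286	292.071	290.735	1.20165	0.13453	195.186
9.52877	252.549	251.279	1.13214	0.137275	172.822
10.0297	221.386	220.18	1.0656	0.139832	154.868
10.5569	193.895	192.751	1.00214	0.142197	138.431
11.1119	169.666	168.58	0.941793	0.144371	123.445
11.6961	148.326	147.295	0.884574	0.146353	109.83
12.3109	129.445	128.466	0.830446	0.148147	97.4226
12.9581	112.894	111.964	0.779332	0.149758	86.2607
13.6393	98.3953	97.513	0.73112	0.151193	76.2458
14.3563	85.7041	84.866	0.68567	0.152459	67.2824
15.111	74.6026	73.8062	0.642819	0.153565	59.2789
15.9054	64.8983	64.1414	0.602393	0.154521	52.148
16.7416	56.4214	55.7018	0.564215	0.155335	45.8078
17.6217	49.0216	48.3375	0.528116	0.156015	40.1816
18.548	42.5528	41.9023	0.493939	0.15657	35.1865
19.5231	36.9133	36.2948	0.461546	0.157006	30.7695
20.5494	32.0074	31.4192	0.430818	0.157328	26.8764
21.6297	27.7419	27.1827	0.401659	0.157542	23.4501
22.7667	24.0351	23.5034	0.373991	0.157652	20.4387
23.9636	20.8155	20.3101	0.347753	0.157661	17.7955
25.2233	18.0206	17.5402	0.322897	0.157571	15.4786
26.5493	15.5959	15.1391	0.299387	0.157384	13.4503
27.945	13.4879	13.0536	0.277194	0.157103	11.6719
29.4141	11.6626	11.2496	0.256293	0.156729	10.12
30.9603	10.0832	9.69029	0.236659	0.156264	8.7678
32.5879	8.71721	8.34324	0.218267	0.155709	7.59059
34.3011	7.5362	7.18005	0.201088	0.155067	6.5667
36.1042	6.51552	6.17609	0.185088	0.154339	5.67695
38.0022	5.63374	5.30999	0.170227	0.15353	4.90443
40	4.86898	4.55988	0.156459	0.15264	4.23126
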