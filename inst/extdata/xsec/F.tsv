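# photon mass interaction coefficients, cm^2/g
# element F  Z=9  A=18.99840 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	5485.57	5484.36	1.19478	0.012435	5484.36
1.05257	4827.26	4826.06	1.18819	0.0136482	4826.06
1.1079	4243.67	4242.47	1.18096	0.0149717	4242.47
1.16614	3725.8	3724.61	1.17306	0.0164135	3724.61
1.22745	3262.12	3260.94	1.16443	0.0179823	3260.94
1.29198	2854.01	2852.83	1.15501	0.0196866	2852.83
1.35989	2495.07	2493.91	1.14475	0.0215352	2493.91
1.43138	2179.64	2178.49	1.13359	0.0235367	2178.49
1.50663	1902.66	1901.52	1.12148	0.0256997	1901.52
1.58583	1659.64	1658.5	1.10837	0.0280322	1658.5
1.6692	1446.56	1445.44	1.09419	0.0305419	1445.44
1.75695	1259.91	1258.79	1.07891	0.0332355	1258.79
1.84931	1096.51	1095.41	1.06247	0.0361189	1095.41
1.94653	953.595	952.511	1.04484	0.0391963	952.511
2.04886	828.688	827.62	1.02598	0.0424709	827.62
2.15656	719.607	718.555	1.00588	0.0459434	718.556
2.26993	624.421	623.387	0.984537	0.0496127	623.387
2.38926	541.425	540.41	0.961942	0.0534752	540.41
2.51487	469.115	468.119	0.938121	0.0575246	468.12
2.64707	406.164	405.189	0.91311	0.0617515	405.189
2.78623	351.387	350.434	0.886962	0.0661439	350.434
2.9327	303.786	302.856	0.859749	0.0706863	302.856
3.08687	262.387	261.48	0.831561	0.0753605	261.48
3.24915	226.449	225.566	0.802506	0.0801452	225.567
3.41995	195.347	194.489	0.772708	0.0850167	194.49
3.59974	168.443	167.611	0.742306	0.0899489	167.612
3.78897	145.183	144.376	0.711451	0.0949142	144.377
3.98816	125.081	124.3	0.680304	0.0998836	124.301
4.19782	107.716	106.963	0.649032	0.104828	106.964
4.41849	92.7254	91.9978	0.617803	0.109717	91.999
4.65077	79.789	79.0877	0.586785	0.114522	79.089
4.89526	68.631	67.9557	0.556142	0.119216	67.9571
5.1526	59.0115	58.3617	0.526028	0.123773	58.3632
5.42347	50.7222	50.0974	0.496586	0.12817	50.0991
5.70858	43.5824	42.9821	0.467945	0.132386	42.9839
6.00868	37.4357	36.8591	0.440218	0.136404	36.861
6.32456	32.1464	31.5927	0.413496	0.14021	31.5947
6.65703	27.5969	27.0653	0.387856	0.143793	27.0675
7.00699	23.6857	23.1752	0.363352	0.147147	23.1775
7.37535	20.3246	19.8343	0.340019	0.150266	19.8368
7.76307	17.4377	16.9667	0.317876	0.153151	16.9693
8.17117	14.9591	14.5064	0.296922	0.155803	14.5092
8.60072	12.8321	12.3967	0.277147	0.158226	12.3997
9.05286	11.0058	10.5868	0.258528	0.160425	10.59
9.52877	9.43807	9.03463	0.241031	0.162407	9.03795
10.0297	8.096	7.7072	0.224618	0.164181	7.7107
10.5569	6.94742	6.57242	0.209246	0.165754	6.5761
11.1119	5.96469	5.60268	0.194868	0.167136	5.60655
11.6961	5.12406	4.77429	0.181432	0.168336	4.77835
12.3109	4.40515	4.0669	0.168888	0.169363	4.07117
12.9581	3.79016	3.46276	0.157181	0.170226	3.46723
13.6393	3.26292	2.94573	0.146259	0.170935	2.95042
14.3563	2.81279	2.50523	0.136067	0.171499	2.51013
15.111	2.4285	2.13002	0.126553	0.171927	2.13516
15.9054	2.10042	1.81053	0.117665	0.172227	1.8159
16.7416	1.8203	1.53854	0.109357	0.172407	1.54415
17.6217	1.58111	1.30706	0.101585	0.172474	1.31292
18.548	1.37684	1.1101	0.0943076	0.172434	1.11623
19.5231	1.20236	0.942572	0.0874903	0.172293	0.948964
20.5494	1.05327	0.800109	0.081101	0.172056	0.806777
21.6297	0.925834	0.678995	0.0751121	0.171727	0.685947
22.7667	0.816868	0.576058	0.0694992	0.171311	0.583305
23.9636	0.723646	0.488595	0.0642409	0.17081	0.496144
25.2233	0.643845	0.414299	0.0593187	0.170228	0.422159
26.5493	0.575489	0.351205	0.054716	0.169567	0.359386
27.945	0.516281	0.297034	0.0504181	0.16883	0.305542
29.4141	0.465569	0.251139	0.0464114	0.168019	0.259985
30.9603	0.422144	0.212326	0.0426831	0.167135	0.221516
32.5879	0.384906	0.179503	0.039221	0.166182	0.189046
34.3011	0.352921	0.151747	0.0360128	0.165162	0.16165
36.1042	0.325398	0.128276	0.033046	0.164076	0.138547
38.0022	0.301665	0.108431	0.0303081	0.162926	0.119076
40	0.281153	0.0916515	0.0277861	0.161715	0.102678
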