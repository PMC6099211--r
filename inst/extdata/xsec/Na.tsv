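# photon mass interaction coefficients, cm^2/g
# element Na  Z=11  A=22.98977 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	593.922	592.484	1.41665	0.0216923	592.484
1.05257	518.365	516.936	1.40528	0.0233878	516.936
1.1079	6421.92	6420.5	1.39326	0.0251737	6420.5
1.16614	6145.64	6144.23	1.38057	0.0270485	6144.23
1.22745	5373.95	5372.55	1.36723	0.0290099	5372.55
1.29198	4700.25	4698.87	1.35325	0.0310548	4698.87
1.35989	4112.09	4110.71	1.33864	0.0331798	4110.71
1.43138	3607.26	3605.91	1.32343	0.035381	3605.91
1.50663	3169.52	3168.18	1.30762	0.0376545	3168.18
1.58583	2782.33	2781	1.29125	0.0399969	2781
1.6692	2440.17	2438.85	1.27432	0.0424051	2438.85
1.75695	2138.11	2136.81	1.25683	0.0448771	2136.81
1.84931	1871.7	1870.41	1.23879	0.0474123	1870.41
1.94653	1636.96	1635.69	1.22018	0.0500114	1635.69
2.04886	1430.34	1429.09	1.20098	0.0526769	1429.09
2.15656	1248.54	1247.31	1.18116	0.055413	1247.31
2.26993	1088.33	1087.11	1.16066	0.0582253	1087.11
2.38926	947.983	946.782	1.13943	0.0611207	946.783
2.51487	825.144	823.962	1.11741	0.0641067	823.963
2.64707	717.706	716.544	1.09454	0.0671908	716.545
2.78623	623.81	622.669	1.07075	0.07038	622.669
2.9327	541.811	540.691	1.046	0.07368	540.691
3.08687	470.067	468.97	1.02024	0.0770948	468.97
3.24915	407.455	406.381	0.993452	0.0806257	406.382
3.41995	352.99	351.94	0.965626	0.0842715	351.941
3.59974	305.639	304.614	0.936779	0.0880277	304.615
3.78897	264.497	263.498	0.906949	0.0918869	263.499
3.98816	228.769	227.797	0.876197	0.0958382	227.798
4.19782	197.763	196.818	0.84461	0.0998675	196.819
4.41849	170.869	169.953	0.812295	0.103958	169.954
4.65077	147.553	146.665	0.779383	0.108089	146.666
4.89526	127.271	126.413	0.746024	0.11224	126.414
5.1526	109.734	108.905	0.712382	0.116385	108.906
5.42347	94.5763	93.7771	0.678632	0.120501	93.7786
5.70858	81.4817	80.7122	0.64496	0.124561	80.7138
6.00868	70.1743	69.4342	0.611548	0.12854	69.436
6.32456	60.4146	59.7036	0.578577	0.132414	59.7055
6.65703	51.9945	51.3121	0.546216	0.136159	51.3142
7.00699	44.7332	44.0789	0.514623	0.139757	44.0811
7.37535	38.4743	37.8471	0.483935	0.143188	37.8495
7.76307	33.0815	32.4808	0.45427	0.146439	32.4834
8.17117	28.4372	27.862	0.425726	0.149498	27.8647
8.60072	24.4392	23.8885	0.398375	0.152357	23.8914
9.05286	20.9915	20.4642	0.372272	0.155011	20.4673
9.52877	18.0156	17.5107	0.347451	0.157456	17.5139
10.0297	15.4616	14.978	0.323928	0.159692	14.9815
10.5569	13.2704	12.807	0.301704	0.16172	12.8107
11.1119	11.391	10.9467	0.280767	0.163545	10.9506
11.6961	9.77954	9.35327	0.261094	0.16517	9.35732
12.3109	8.39811	7.98886	0.242649	0.166601	7.99312
12.9581	7.21424	6.82101	0.22539	0.167845	6.82548
13.6393	6.19994	5.82176	0.209268	0.16891	5.82645
14.3563	5.33112	4.96709	0.194227	0.169804	4.97201
15.111	4.58709	4.23634	0.180208	0.170536	4.2415
15.9054	3.95005	3.61179	0.16715	0.171113	3.61719
16.7416	3.40472	3.07819	0.15499	0.171545	3.08384
17.6217	2.93797	2.62247	0.143667	0.17184	2.62838
18.548	2.53853	2.2334	0.133122	0.172006	2.23957
19.5231	2.19671	1.90136	0.1233	0.172049	1.90781
20.5494	1.90422	1.61809	0.114152	0.171977	1.62482
21.6297	1.65395	1.37653	0.10563	0.171795	1.38354
22.7667	1.4398	1.1706	0.0976957	0.171509	1.17791
23.9636	1.25647	0.995033	0.0903103	0.171124	1.00265
25.2233	1.09964	0.845551	0.0834413	0.170643	0.853484
26.5493	0.96545	0.71832	0.0770584	0.170072	0.726575
27.945	0.850609	0.610062	0.0711338	0.169413	0.618648
29.4141	0.752275	0.517963	0.0656416	0.16867	0.526888
30.9603	0.668039	0.439635	0.0605578	0.167846	0.448906
32.5879	0.595843	0.373039	0.0558591	0.166945	0.382664
34.3011	0.533927	0.316435	0.0515234	0.165969	0.326422
36.1042	0.480788	0.268338	0.0475293	0.164921	0.278694
38.0022	0.435142	0.227483	0.0438561	0.163804	0.238215
40	0.395892	0.192789	0.0404834	0.16262	0.203904
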