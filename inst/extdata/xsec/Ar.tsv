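# photon mass interaction coefficients, cm^2/g
# element Ar  Z=18  A=39.94800 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	3035.38	3033.12	2.24307	0.0146788	3033.12
1.05257	2662.92	2660.67	2.22788	0.0160741	2660.67
1.1079	2335.05	2332.82	2.21133	0.0175882	2332.82
1.16614	2046.6	2044.39	2.19334	0.019228	2044.39
1.22745	1792.95	1790.76	2.1738	0.0210009	1790.76
1.29198	1569.94	1567.76	2.15263	0.0229136	1567.76
1.35989	1373.68	1371.52	2.12974	0.0249725	1371.52
1.43138	1201.45	1199.32	2.10505	0.0271834	1199.32
1.50663	1050.39	1048.28	2.07848	0.0295514	1048.28
1.58583	917.955	915.873	2.04998	0.0320803	915.873
1.6692	801.904	799.85	2.01948	0.034773	799.85
1.75695	700.257	698.232	1.98696	0.0376305	698.232
1.84931	611.264	609.271	1.9524	0.0406523	609.271
1.94653	533.385	531.425	1.91579	0.043836	531.426
2.04886	465.26	463.336	1.87716	0.0471767	463.336
2.15656	405.692	403.805	1.83658	0.0506675	403.805
2.26993	353.627	351.779	1.79412	0.054299	351.779
2.38926	308.139	306.331	1.74988	0.0580591	306.331
2.51487	268.411	266.645	1.70402	0.0619334	266.646
2.64707	233.728	232.005	1.65669	0.0659053	232.006
2.78623	203.46	201.782	1.60809	0.069956	201.783
2.9327	177.055	175.423	1.55843	0.0740648	175.423
3.08687	153.96	152.374	1.50795	0.0782098	152.375
3.1981	139.738	138.184	1.47273	0.0810827	138.185
3.2077	1371.64	1370.09	1.46973	0.0813263	1241.79
3.24915	1328.7	1327.16	1.4569	0.0823681	1204.47
3.41995	1168.29	1166.8	1.40554	0.0865164	1064.32
3.59974	1024.88	1023.44	1.35413	0.0906315	938.037
3.78897	898.422	897.025	1.30291	0.0946908	825.912
3.98816	786.994	785.643	1.25215	0.098673	726.471
4.19782	688.908	687.604	1.20208	0.102558	638.402
4.41849	602.705	601.446	1.1529	0.106329	560.559
4.65077	526.872	525.657	1.1048	0.10997	491.708
4.89526	460.207	459.036	1.05795	0.113468	430.87
5.1526	401.666	400.537	1.01246	0.116814	377.188
5.42347	350.301	349.212	0.968434	0.12	329.872
5.70858	305.267	304.218	0.925924	0.123025	288.212
6.00868	265.818	264.807	0.884946	0.125886	251.571
6.32456	231.28	230.306	0.845484	0.128588	219.369
6.65703	201.012	200.073	0.807488	0.131134	191.047
7.00699	174.578	173.674	0.77088	0.133531	166.231
7.37535	151.531	150.66	0.735561	0.13579	144.526
7.76307	131.449	130.609	0.701421	0.13792	125.558
8.17117	113.961	113.153	0.668345	0.139929	108.996
8.60072	98.7433	97.9652	0.636224	0.141828	94.5464
9.05286	85.4897	84.7411	0.604961	0.143624	81.9321
9.52877	73.9474	73.2276	0.574477	0.145323	70.9221
10.0297	63.9369	63.2453	0.544716	0.146931	61.3542
10.5569	55.2593	54.5952	0.515645	0.148449	53.045
11.1119	47.7405	47.1033	0.487251	0.149879	45.8335
11.6961	41.2289	40.6181	0.459546	0.151219	39.5786
12.3109	35.5922	35.0072	0.432558	0.152469	34.1569
12.9581	30.7153	30.1554	0.406328	0.153623	29.4604
13.6393	26.4978	25.9622	0.380912	0.15468	25.3947
14.3563	22.8407	22.3287	0.356369	0.155633	21.866
15.111	19.6796	19.1904	0.332763	0.15648	18.8136
15.9054	16.9539	16.4865	0.310154	0.157217	16.1801
16.7416	14.6042	14.1578	0.288596	0.157838	13.909
17.6217	12.5796	12.1531	0.268134	0.158344	11.9514
18.548	10.8355	10.428	0.248797	0.158731	10.2648
19.5231	9.33369	8.94409	0.230602	0.159	8.81245
20.5494	8.0409	7.6682	0.213548	0.159152	7.56237
21.6297	6.92843	6.57162	0.197621	0.159188	6.4869
22.7667	5.97144	5.62954	0.182792	0.159111	5.56209
23.9636	5.14847	4.82052	0.169023	0.158926	4.76722
25.2233	4.44096	4.12606	0.156268	0.158635	4.08435
26.5493	3.8329	3.53019	0.144474	0.158244	3.49798
27.945	3.31041	3.01907	0.133587	0.157756	2.99466
29.4141	2.8616	2.58088	0.12355	0.157176	2.56289
30.9603	2.47618	2.20537	0.114306	0.15651	2.19267
32.5879	2.14527	1.88371	0.1058	0.15576	1.87539
34.3011	1.86121	1.6083	0.0979785	0.154931	1.60359
36.1042	1.6174	1.37258	0.09079	0.154027	1.37089
38.0022	1.40816	1.17092	0.0841865	0.153052	1.17175
40	1.22861	0.998475	0.0781238	0.152009	1.00142
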