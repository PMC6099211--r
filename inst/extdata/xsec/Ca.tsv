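# photon mass interaction coefficients, cm^2/g
# element Ca  Z=20  A=40.07800 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	4630.23	4627.57	2.64174	0.0264682	4627.57
1.05257	4072.71	4070.07	2.6165	0.0285403	4070.07
1.1079	3580.07	3577.45	2.58981	0.0307201	3577.45
1.16614	3145.08	3142.48	2.56169	0.0330058	3142.48
1.22745	2761.27	2758.7	2.53214	0.0353948	2758.7
1.29198	2422.85	2420.31	2.5012	0.0378837	2420.31
1.35989	2124.67	2122.16	2.46888	0.0404688	2122.16
1.43138	1861.51	1859.03	2.43524	0.0431456	1859.03
1.50663	1629.73	1627.29	2.40031	0.0459096	1627.29
1.58583	1426.16	1423.75	2.36412	0.0487564	1423.75
1.6692	1247.46	1245.08	2.32671	0.0516817	1245.08
1.75695	1090.64	1088.3	2.28812	0.0546817	1088.3
1.84931	952.867	950.561	2.24836	0.0577532	950.561
1.94653	832.17	829.902	2.20746	0.0608937	829.902
2.04886	726.484	724.255	2.16542	0.0641013	724.255
2.15656	633.984	631.794	2.12225	0.0673751	631.795
2.26993	553.059	550.911	2.07792	0.0707145	550.911
2.38926	482.293	480.186	2.03243	0.0741194	480.187
2.51487	420.435	418.371	1.98576	0.0775897	418.372
2.64707	366.386	364.367	1.9379	0.0811252	364.368
2.78623	319.18	317.206	1.88884	0.084725	317.207
2.9327	277.966	276.039	1.83859	0.0883869	276.04
3.08687	241.869	239.99	1.78718	0.0921075	239.99
3.24915	210.324	208.494	1.73466	0.0958812	208.495
3.41995	182.859	181.078	1.68111	0.0997002	181.079
3.59974	158.95	157.22	1.62665	0.103554	157.221
3.78897	138.143	136.465	1.57143	0.107429	136.466
3.98816	120.04	118.413	1.51564	0.111311	118.414
4.03204	116.489	114.873	1.50367	0.112139	114.874
4.04416	1082.67	1081.05	1.50039	0.112366	944.392
4.19782	974.81	973.236	1.4595	0.115181	854.707
4.41849	853.786	852.264	1.40326	0.119019	753.653
4.65077	748.792	747.322	1.34718	0.122804	665.172
4.89526	656.167	654.749	1.29154	0.126517	586.37
5.1526	574.524	573.157	1.23661	0.130134	516.289
5.42347	502.575	501.258	1.18266	0.133638	454.008
5.70858	439.262	437.995	1.12992	0.13701	398.771
6.00868	383.622	382.404	1.07861	0.140236	349.869
6.32456	334.766	333.594	1.0289	0.143304	306.63
6.65703	291.901	290.774	0.980902	0.146205	268.445
7.00699	254.323	253.239	0.9347	0.148936	234.765
7.37535	221.411	220.369	0.890317	0.151496	205.096
7.76307	192.61	191.608	0.847732	0.153887	178.992
8.17117	167.422	166.459	0.806884	0.156114	156.046
8.60072	145.415	144.489	0.767678	0.158187	135.903
9.05286	126.187	125.297	0.729997	0.160112	118.224
9.52877	109.38	108.525	0.69371	0.161902	102.705
10.0297	94.769	93.9467	0.65869	0.163565	89.1614
10.5569	82.0728	81.2828	0.624815	0.165109	77.3501
11.1119	71.0463	70.2878	0.591983	0.166543	67.0577
11.6961	61.4747	60.7467	0.560114	0.167872	58.0954
12.3109	53.1702	52.472	0.529151	0.1691	50.2972
12.9581	45.9688	45.2995	0.499064	0.170229	43.5167
13.6393	39.727	39.0859	0.469845	0.17126	37.6255
14.3563	34.3196	33.7059	0.441504	0.172192	32.5106
15.111	29.6375	29.0504	0.41407	0.173023	28.0727
15.9054	25.5854	25.024	0.387583	0.173751	24.2251
16.7416	22.0801	21.5437	0.36209	0.174373	20.8915
17.6217	19.0481	18.5356	0.337641	0.174886	18.0038
18.548	16.4217	15.9322	0.314287	0.175288	15.4993
19.5231	14.1562	13.6886	0.29207	0.175575	13.3367
20.5494	12.2028	11.756	0.271026	0.175748	11.4704
21.6297	10.519	10.092	0.251174	0.175804	9.86066
22.7667	9.06809	8.65982	0.232525	0.175744	8.47288
23.9636	7.81836	7.42772	0.21507	0.17557	7.27711
25.2233	6.74226	6.36819	0.198788	0.175284	6.24731
26.5493	5.816	5.45746	0.183647	0.174889	5.36092
27.945	5.01091	4.66692	0.169602	0.174387	4.59044
29.4141	4.31941	3.98903	0.156603	0.173784	3.92895
30.9603	3.72646	3.40878	0.144595	0.173082	3.36212
32.5879	3.21803	2.91223	0.133518	0.172287	2.87654
34.3011	2.78212	2.4874	0.123314	0.171403	2.46071
36.1042	2.40838	2.12403	0.113922	0.170433	2.10472
38.0022	2.08796	1.81329	0.105287	0.169382	1.80007
40	1.81324	1.54764	0.0973511	0.168254	1.53943
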