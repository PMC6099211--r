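# photon mass interaction coefficients, cm^2/g
# element P  Z=15  A=30.97376 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	1794.48	1792.5	1.95898	0.0215229	1792.5
1.05257	1571.49	1569.52	1.94144	0.0234535	1569.52
1.1079	1375.65	1373.7	1.92252	0.0255264	1373.7
1.16614	1203.73	1201.8	1.90216	0.0277462	1201.8
1.22745	1052.89	1050.98	1.88033	0.0301166	1050.98
1.29198	920.593	918.703	1.85698	0.0326402	918.703
1.35989	804.61	802.743	1.83208	0.0353183	802.743
1.43138	702.973	701.13	1.80562	0.0381506	701.13
1.50663	613.944	612.125	1.77759	0.0411351	612.125
1.58583	535.989	534.197	1.74803	0.0442677	534.197
1.6692	467.76	465.995	1.71695	0.0475425	465.995
1.75695	408.065	406.33	1.68443	0.0509513	406.33
1.84931	355.858	354.153	1.65052	0.054484	354.153
1.94653	310.218	308.544	1.61534	0.0581284	308.544
2.04886	270.333	268.692	1.57899	0.0618702	268.692
2.14228	239.748	238.137	1.54651	0.0651937	238.137
2.14872	2642.75	2641.14	1.5443	0.0654192	2507.28
2.15656	2623.36	2621.75	1.54161	0.0656936	2489.36
2.26993	2346.13	2344.56	1.50334	0.0695814	2232.07
2.38926	2056.75	2055.21	1.46435	0.0735152	1961.53
2.51487	1802.84	1801.34	1.42479	0.0774762	1723.33
2.64707	1580.08	1578.61	1.38483	0.0814452	1513.67
2.78623	1384.69	1383.26	1.34466	0.0854033	1329.2
2.9327	1213.53	1212.13	1.30444	0.0893322	1167.12
3.08687	1062.43	1061.07	1.26433	0.0932148	1023.64
3.24915	929.281	927.96	1.22447	0.0970353	896.858
3.41995	812.205	810.919	1.185	0.10078	785.098
3.59974	709.325	708.075	1.14604	0.104437	686.655
3.78897	618.972	617.756	1.10768	0.107996	600.002
3.98816	539.721	538.54	1.06999	0.111451	523.836
4.19782	470.264	469.117	1.03301	0.114798	456.948
4.41849	409.197	408.083	0.996765	0.118036	398.026
4.65077	355.679	354.596	0.961239	0.121166	346.295
4.89526	308.976	307.925	0.926399	0.124192	301.076
5.1526	268.246	267.227	0.892186	0.12712	261.581
5.42347	232.749	231.76	0.85853	0.129957	227.108
5.70858	201.83	200.872	0.82535	0.132712	197.042
6.00868	174.918	173.99	0.792564	0.135393	170.838
6.32456	151.506	150.608	0.760101	0.138006	148.017
6.65703	131.154	130.285	0.727903	0.140557	128.156
7.00699	113.471	112.632	0.695933	0.143049	110.883
7.37535	98.1175	97.3078	0.664179	0.145483	95.8733
7.76307	84.7951	84.0146	0.632652	0.147857	82.8385
8.17117	73.2422	72.4906	0.601391	0.150167	71.5271
8.60072	63.2298	62.5069	0.570455	0.152407	61.7182
9.05286	54.554	53.8596	0.539925	0.154569	53.2146
9.52877	47.0211	46.3546	0.509896	0.156644	45.828
10.0297	40.4971	39.858	0.480474	0.158621	39.4285
10.5569	34.8704	34.2581	0.451772	0.160491	33.9083
11.1119	30.0193	29.4332	0.4239	0.162244	29.1485
11.6961	25.8385	25.2776	0.396965	0.163869	25.0462
12.3109	22.2364	21.7	0.371063	0.16536	21.5122
12.9581	19.1342	18.6212	0.346275	0.166709	18.4691
13.6393	16.4633	15.9728	0.322662	0.167911	15.8499
14.3563	14.1647	13.6954	0.300266	0.168965	13.5964
15.111	12.187	11.738	0.279107	0.169868	11.6586
15.9054	10.4861	10.0563	0.259188	0.170623	9.9928
16.7416	9.02368	8.61196	0.24049	0.171231	8.56158
17.6217	7.76674	7.37206	0.222982	0.171698	7.33242
18.548	6.68675	6.3081	0.206622	0.172026	6.27726
19.5231	5.75906	5.39548	0.191358	0.172222	5.37186
20.5494	4.96242	4.61299	0.177136	0.172291	4.59532
21.6297	4.27851	3.94237	0.163899	0.172239	3.92959
22.7667	3.69151	3.36785	0.151588	0.172072	3.35912
23.9636	3.18782	2.87587	0.140151	0.171794	2.87049
25.2233	2.7557	2.45475	0.129535	0.171411	2.45216
26.5493	2.38505	2.09443	0.119693	0.170927	2.09418
27.945	2.06592	1.785	0.110578	0.170346	1.78672
29.4141	1.79251	1.52069	0.10215	0.169673	1.52408
30.9603	1.55841	1.29513	0.0943678	0.168912	1.29995
32.5879	1.35796	1.1027	0.0871933	0.168065	1.10874
34.3011	1.1863	0.938576	0.0805896	0.167137	0.945693
36.1042	1.03929	0.798643	0.0745205	0.166131	0.806704
38.0022	0.913369	0.679368	0.0689508	0.16505	0.688272
40	0.805478	0.577734	0.0638458	0.163898	0.587398
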