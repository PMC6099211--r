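# photon mass interaction coefficients, cm^2/g
# element S  Z=16  A=32.06500 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	2285.75	2283.55	2.1732	0.020004	2283.55
1.05257	2002.79	2000.61	2.15538	0.0218441	2000.61
1.1079	1754.12	1751.96	2.13608	0.0238283	1751.96
1.16614	1535.69	1533.55	2.11523	0.0259632	1533.55
1.22745	1343.92	1341.8	2.09274	0.0282544	1341.8
1.29198	1175.63	1173.53	2.06857	0.030707	1173.53
1.35989	1028.01	1025.93	2.04265	0.0333249	1025.93
1.43138	898.579	896.528	2.01493	0.0361105	896.528
1.50663	785.144	783.12	1.9854	0.039065	783.12
1.58583	685.771	683.775	1.95403	0.0421877	683.775
1.6692	598.752	596.786	1.92082	0.0454758	596.786
1.75695	522.582	520.648	1.88581	0.0489244	520.648
1.84931	455.936	454.035	1.84905	0.0525264	454.035
1.94653	397.646	395.779	1.81059	0.0562724	395.779
2.04886	346.684	344.853	1.77055	0.0601502	344.853
2.15656	302.145	300.352	1.72905	0.0641457	300.352
2.26993	263.235	261.481	1.68621	0.0682424	261.481
2.38926	229.256	227.542	1.64222	0.0724221	227.542
2.46829	209.952	208.263	1.61376	0.0751107	208.264
2.47571	2219.46	2217.77	1.61112	0.0753596	2078.96
2.51487	2142.74	2141.07	1.59726	0.0766646	2009.15
2.64707	1893.24	1891.61	1.55152	0.0809488	1780.88
2.78623	1659.29	1657.7	1.50521	0.0852528	1565.51
2.9327	1454.49	1452.94	1.45854	0.0895544	1376.17
3.08687	1275.42	1273.92	1.41175	0.0938314	1209.97
3.24915	1117.78	1116.32	1.36503	0.0980626	1063.08
3.41995	978.675	977.254	1.31859	0.102228	932.977
3.59974	856.219	854.84	1.27262	0.106308	818.044
3.78897	748.507	747.17	1.22729	0.110288	716.614
3.98816	653.842	652.545	1.18275	0.114153	627.192
4.19782	570.709	569.452	1.13913	0.117891	548.433
4.41849	497.746	496.528	1.09652	0.121495	479.116
4.65077	433.765	432.585	1.05497	0.12496	418.174
4.89526	377.722	376.579	1.01452	0.128282	364.66
5.1526	328.449	327.342	0.97516	0.131465	317.5
5.42347	285.382	284.311	0.936849	0.134512	276.19
5.70858	247.815	246.778	0.899523	0.137431	240.081
6.00868	215.066	214.063	0.863096	0.140229	208.544
6.32456	186.535	185.565	0.82747	0.142916	181.02
6.65703	161.695	160.757	0.792545	0.145501	157.017
7.00699	140.082	139.176	0.758228	0.147994	136.1
7.37535	121.288	120.413	0.724438	0.150401	117.886
7.76307	104.957	104.113	0.691119	0.152727	102.037
8.17117	90.7739	89.9607	0.658235	0.154976	88.2575
8.60072	78.4645	77.6816	0.625779	0.157147	76.2849
9.05286	67.7793	67.0262	0.59377	0.159239	65.882
9.52877	58.5092	57.7857	0.562249	0.161248	56.8492
10.0297	50.4882	49.7937	0.531277	0.163168	49.0279
10.5569	43.5512	42.8853	0.500935	0.164992	42.2594
11.1119	37.5329	36.8948	0.471312	0.166713	36.3842
11.6961	32.3309	31.7201	0.442506	0.168322	31.3039
12.3109	27.8443	27.2598	0.414616	0.16981	26.921
12.9581	23.9758	23.4169	0.387735	0.171171	23.1414
13.6393	20.6417	20.1074	0.36195	0.172398	19.8837
14.3563	17.7691	17.2583	0.337331	0.173486	17.077
15.111	15.2951	14.8067	0.313932	0.174431	14.6602
15.9054	13.1651	12.6981	0.291787	0.175231	12.5799
16.7416	11.3319	10.8851	0.270911	0.175886	10.7901
17.6217	9.75472	9.32703	0.251299	0.176398	9.25109
18.548	8.3983	7.9886	0.232927	0.176769	7.92822
19.5231	7.2321	6.83934	0.215758	0.177003	6.79171
20.5494	6.22978	5.85293	0.199745	0.177106	5.81575
21.6297	5.36857	5.00666	0.184829	0.177082	4.97806
22.7667	4.62881	4.28092	0.170949	0.176938	4.25937
23.9636	3.99355	3.65883	0.158042	0.176679	3.64308
25.2233	3.44816	3.1258	0.146045	0.176311	3.11484
26.5493	2.98002	2.66929	0.134897	0.175839	2.66229
27.945	2.57667	2.27686	0.124541	0.175268	2.27317
29.4141	2.23089	1.94136	0.114925	0.174602	1.94042
30.9603	1.93465	1.6548	0.106001	0.173846	1.65618
32.5879	1.68085	1.41012	0.0977261	0.173004	1.41344
34.3011	1.46339	1.20125	0.0900608	0.172078	1.20623
36.1042	1.27706	1.02302	0.082969	0.171072	1.02942
38.0022	1.11737	0.87096	0.0764172	0.16999	0.878596
40	0.980487	0.74128	0.0703734	0.168834	0.749997
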