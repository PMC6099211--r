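# photon mass interaction coefficients, cm^2/g
# element Rh  Z=45  A=102.90550 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	5892.44	5886.91	5.52564	0.011053	5886.91
1.05257	5262.72	5257.21	5.49797	0.0120688	5257.21
1.1079	4695.37	4689.89	5.46796	0.0131657	4689.89
1.16614	4185.38	4179.93	5.43548	0.0143479	4179.93
1.22745	3727.6	3722.19	5.40039	0.0156197	3722.19
1.29198	3314.39	3309.01	5.36255	0.016985	3309.01
1.35989	2944.7	2939.36	5.32183	0.0184477	2939.36
1.43138	2614.65	2609.35	5.2781	0.0200114	2609.35
1.50663	2320.16	2314.91	5.23124	0.0216793	2314.91
1.58583	2057.6	2052.4	5.18114	0.0234543	2052.4
1.6692	1823.64	1818.49	5.12768	0.025339	1818.49
1.75695	1615.28	1610.18	5.07078	0.0273353	1610.18
1.84931	1429.83	1424.79	5.01034	0.0294449	1424.79
1.94653	1264.88	1259.91	4.9463	0.031669	1259.91
2.04886	1118.02	1113.11	4.8786	0.0340079	1113.11
2.15656	987.383	982.54	4.80719	0.0364619	982.54
2.26993	871.514	866.743	4.73205	0.0390299	866.743
2.38926	768.865	764.171	4.65317	0.0417107	764.171
2.51487	677.978	673.363	4.57058	0.0445016	673.364
2.64707	597.535	593.004	4.48432	0.0473993	593.004
2.78623	526.398	521.953	4.39448	0.0503992	521.953
2.9327	463.522	459.167	4.30116	0.0534954	459.168
2.99929	438.328	434.014	4.25922	0.0548808	434.014
3.00831	1518.93	1514.62	4.25356	0.0550672	1514.62
3.08687	1432.25	1427.98	4.20454	0.0566806	1427.98
3.14138	1374.95	1370.73	4.17081	0.0577877	1370.73
3.15082	1879.36	1875.13	4.16499	0.0579784	1875.13
3.24915	1741.98	1737.82	4.10482	0.0599461	1737.82
3.40678	1542.9	1538.83	4.01004	0.0630286	1538.83
3.41702	1760.97	1756.91	4.00396	0.0632256	1756.91
3.41995	1757.21	1753.15	4.00222	0.063282	1753.15
3.59974	1546.53	1542.57	3.89705	0.0666769	1542.57
3.78897	1361.41	1357.55	3.78962	0.0701183	1357.55
3.98816	1197.36	1193.6	3.68028	0.073593	1193.6
4.19782	1052.03	1048.38	3.56941	0.0770867	1048.38
4.41849	923.613	920.075	3.45739	0.0805853	920.076
4.65077	810.155	806.727	3.34465	0.0840739	806.728
4.89526	710.175	706.856	3.23158	0.0875381	706.857
5.1526	622.149	618.94	3.11859	0.0909637	618.941
5.42347	544.703	541.603	3.00608	0.0943369	541.604
5.70858	476.614	473.621	2.89444	0.0976445	473.623
6.00868	416.786	413.901	2.78403	0.100874	413.902
6.32456	364.182	361.403	2.67519	0.104016	361.405
6.65703	318.031	315.355	2.56821	0.107058	315.357
7.00699	277.594	275.02	2.46335	0.109995	275.022
7.37535	242.19	239.716	2.3608	0.112819	239.718
7.76307	211.22	208.844	2.26068	0.115527	208.846
8.17117	184.142	181.861	2.16307	0.118118	181.863
8.60072	160.478	158.289	2.06796	0.120591	158.291
9.05286	139.781	137.683	1.97528	0.122949	137.686
9.52877	121.677	119.667	1.88493	0.125196	119.669
10.0297	105.889	103.965	1.79679	0.127337	103.968
10.5569	92.1322	90.2922	1.7107	0.129374	90.2951
11.1119	80.1515	78.3936	1.62654	0.131314	78.3968
11.6961	69.7198	68.0424	1.54422	0.133157	68.0457
12.3109	60.6381	59.0395	1.46368	0.134907	59.043
12.9581	52.7337	51.2122	1.38493	0.136563	51.2159
13.6393	45.8442	44.3981	1.30803	0.138123	44.402
14.3563	39.843	38.4703	1.23308	0.139583	38.4745
15.111	34.6237	33.3225	1.16022	0.140941	33.3269
15.9054	30.0846	28.8528	1.08964	0.14219	28.8574
16.7416	26.1427	24.9779	1.02151	0.143327	24.9827
17.6217	22.7195	21.6192	0.956022	0.144345	21.6242
18.548	19.7469	18.7083	0.893352	0.145241	18.7136
19.5231	17.1656	16.186	0.833647	0.146011	16.1916
20.5494	14.9244	14.0007	0.777022	0.146653	14.0066
21.6297	12.9785	12.1078	0.723551	0.147166	12.114
22.7667	11.2892	10.4684	0.673267	0.14755	10.4749
23.1851	10.7442	9.94035	0.656165	0.147656	9.94691
23.2547	66.5535	65.7525	0.653385	0.147672	27.4553
23.9636	61.1494	60.3754	0.626163	0.147807	26.2512
25.2233	53.3868	52.6567	0.58219	0.147938	24.3829
26.5493	46.6985	46.0093	0.541269	0.147947	22.5402
27.945	40.8016	40.1504	0.503292	0.147838	20.6943
29.4141	35.6253	35.0096	0.468132	0.147616	18.8936
30.9603	31.0778	30.4948	0.435642	0.147286	17.1599
32.5879	27.0896	26.537	0.405671	0.146852	15.5141
34.3011	23.6031	23.0787	0.378056	0.14632	13.973
36.1042	20.5571	20.0587	0.352639	0.145695	12.5417
38.0022	17.8974	17.4231	0.32926	0.144982	11.2219
40	15.5763	15.1244	0.307767	0.144185	10.0122
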