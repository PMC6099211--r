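# photon mass interaction coefficients, cm^2/g
# element Cl  Z=17  A=35.45300 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	2669.38	2667.12	2.23767	0.0173195	2667.12
1.05257	2341.21	2338.97	2.22097	0.018944	2338.97
1.1079	2052.13	2049.91	2.20282	0.0207015	2049.91
1.16614	1797.65	1795.45	2.18314	0.0225993	1795.45
1.22745	1574.05	1571.86	2.16184	0.0246442	1571.86
1.29198	1377.67	1375.51	2.13884	0.0268423	1375.51
1.35989	1205.29	1203.15	2.11407	0.0291992	1203.15
1.43138	1054.05	1051.93	2.08747	0.0317195	1051.93
1.50663	921.42	919.327	2.05896	0.0344066	919.327
1.58583	805.159	803.093	2.02853	0.0372626	803.093
1.6692	703.294	701.258	1.99612	0.0402877	701.258
1.75695	614.083	612.078	1.96175	0.0434806	612.078
1.84931	535.986	534.014	1.92542	0.0468376	534.014
1.94653	467.649	465.711	1.88717	0.0503529	465.711
2.04886	407.875	405.974	1.84707	0.0540182	405.974
2.15656	355.613	353.75	1.80519	0.057823	353.75
2.26993	309.937	308.114	1.76167	0.061754	308.114
2.38926	270.033	268.251	1.71663	0.0657958	268.251
2.51487	235.186	233.445	1.67025	0.0699308	233.446
2.64707	204.765	203.068	1.62272	0.0741393	203.068
2.78623	178.219	176.566	1.57425	0.0784002	176.567
2.81817	172.79	171.147	1.56336	0.0793529	171.148
2.82663	1757.48	1755.84	1.56049	0.0796039	1620.08
2.9327	1610.01	1608.4	1.52506	0.0826911	1488.54
3.08687	1412.49	1410.93	1.47539	0.086989	1311.03
3.24915	1239.03	1237.51	1.42548	0.0912707	1154.27
3.41995	1086.11	1084.64	1.37558	0.0955131	1015.32
3.59974	951.4	949.974	1.32592	0.0996943	892.297
3.78897	832.975	831.595	1.27674	0.103793	783.627
3.98816	728.791	727.455	1.22823	0.107791	687.59
4.19782	637.145	635.853	1.1806	0.111671	602.748
4.41849	556.593	555.344	1.134	0.115419	527.875
4.65077	485.848	484.641	1.08858	0.119023	461.867
4.89526	423.767	422.601	1.04443	0.122475	403.734
5.1526	369.327	368.2	1.00161	0.125771	352.583
5.42347	321.622	320.533	0.960159	0.128909	307.617
5.70858	279.825	278.773	0.920055	0.131891	268.101
6.00868	243.17	242.154	0.881256	0.134722	233.348
6.32456	211.191	210.209	0.843688	0.13741	202.947
6.65703	183.308	182.36	0.807252	0.139964	176.375
7.00699	159.012	158.098	0.771842	0.142393	153.169
7.37535	137.856	136.974	0.737344	0.144708	132.917
7.76307	119.445	118.595	0.703654	0.146917	115.258
8.17117	103.434	102.615	0.670682	0.149029	99.8724
8.60072	89.5186	88.7292	0.638356	0.15105	86.4772
9.05286	77.4183	76.6587	0.606633	0.152983	74.8109
9.52877	66.8994	66.1691	0.57549	0.15483	64.6545
10.0297	57.7869	57.0854	0.544931	0.15659	55.8447
10.5569	49.8965	49.2232	0.514983	0.158261	48.2076
11.1119	43.0674	42.4219	0.48569	0.15984	41.5912
11.6961	37.1597	36.5413	0.457113	0.161322	35.8624
12.3109	32.0481	31.4561	0.429324	0.162701	30.9017
12.9581	27.6124	27.0461	0.402401	0.16397	26.5942
13.6393	23.7863	23.2448	0.376425	0.165124	22.8768
14.3563	20.4871	19.9695	0.35147	0.166158	19.6703
15.111	17.6433	17.1486	0.327605	0.167067	16.9056
15.9054	15.1929	14.7201	0.304886	0.167846	14.5231
16.7416	13.0822	12.6303	0.283352	0.168495	12.471
17.6217	11.2647	10.8327	0.263025	0.169012	10.7041
18.548	9.70033	9.28702	0.243911	0.169397	9.18368
19.5231	8.35423	7.95858	0.225995	0.169653	7.87587
20.5494	7.19635	6.81732	0.20925	0.169783	6.75148
21.6297	6.20069	5.83726	0.193634	0.16979	5.78525
22.7667	5.34478	4.99601	0.179095	0.16968	4.95532
23.9636	4.60922	4.27419	0.165573	0.169458	4.2428
25.2233	3.97726	3.65513	0.153005	0.169129	3.63137
26.5493	3.43443	3.12441	0.141325	0.168698	3.10693
27.945	2.96629	2.66766	0.130465	0.16817	2.65537
29.4141	2.56465	2.27673	0.120363	0.167552	2.26874
30.9603	2.22029	1.94248	0.110957	0.166848	1.93804
32.5879	1.92502	1.65677	0.10219	0.166061	1.65529
34.3011	1.67185	1.41264	0.0940124	0.165197	1.41363
36.1042	1.45472	1.20409	0.0863779	0.164258	1.20717
38.0022	1.26849	1.026	0.0792483	0.163248	1.03085
40	1.10873	0.873967	0.0725911	0.162169	0.880334
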