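# photon mass interaction coefficients, cm^2/g
# element W  Z=74  A=183.84000 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	3496.6	3488.14	8.44527	0.00828446	3488.14
1.05257	3166.13	3157.71	8.41174	0.00903254	3157.71
1.1079	2863.39	2855	8.37531	0.00984184	2855
1.16614	2588.63	2580.28	8.33581	0.0107157	2580.28
1.22745	2339.25	2330.95	8.29307	0.0116574	2330.95
1.29198	2112.93	2104.67	8.24691	0.0126701	2104.67
1.35989	1907.55	1899.34	8.19716	0.0137565	1899.34
1.43138	1721.19	1713.03	8.14368	0.0149193	1713.03
1.50663	1552.13	1544.02	8.08632	0.0161607	1544.02
1.58583	1398.79	1390.74	8.02496	0.0174825	1390.74
1.6692	1259.75	1251.77	7.95949	0.0188861	1251.77
1.75695	1133.59	1125.68	7.88982	0.0203723	1125.68
1.80649	1070.13	1062.26	7.85022	0.0212137	1062.26
1.81191	19499	19491.1	7.84588	0.021306	19491.1
1.84931	7430.16	7422.32	7.81588	0.0219417	7422.32
1.86879	4939.18	4931.36	7.80023	0.0222729	4931.36
1.87441	16365.4	16357.5	7.79571	0.0223684	16357.5
1.94653	4713.25	4705.49	7.73763	0.0235941	4705.49
2.04886	3694.36	3686.68	7.65503	0.0253291	3686.68
2.15656	3263.86	3256.26	7.56807	0.0271457	3256.26
2.26993	2878.41	2870.9	7.47675	0.0290429	2870.9
2.27758	2854.59	2847.09	7.47061	0.0291702	2847.09
2.28442	3325.55	3318.06	7.46511	0.029284	3318.06
2.38926	2956.49	2949.08	7.38108	0.0310193	2949.08
2.51487	2617.14	2609.82	7.28105	0.0330736	2609.83
2.57104	2482.48	2475.21	7.23659	0.033983	2475.21
2.57876	2636.05	2628.78	7.23049	0.0341076	2628.78
2.64707	2468.65	2461.44	7.17668	0.0352045	2461.44
2.78623	2183.76	2176.65	7.06797	0.0374107	2176.65
2.81537	2130.94	2123.86	7.04535	0.0378679	2123.86
2.82383	2210.35	2203.27	7.0388	0.0380003	2203.27
2.9327	2023.47	2016.48	6.95488	0.0396914	2016.48
3.08687	1795.01	1788.13	6.83742	0.0420457	1788.13
3.24915	1590.38	1583.62	6.71553	0.044473	1583.62
3.41995	1407.97	1401.34	6.58919	0.0469726	1401.34
3.59974	1245.52	1239.01	6.4584	0.0495433	1239.01
3.78897	1100.59	1094.21	6.32314	0.0521836	1094.21
3.98816	971.687	965.449	6.18348	0.054891	965.449
4.19782	857.48	851.382	6.03951	0.057662	851.383
4.41849	756.345	750.393	5.8914	0.0604916	750.394
4.65077	666.748	660.946	5.73939	0.0633735	660.946
4.89526	587.37	581.72	5.58378	0.0662999	581.721
5.1526	517.213	511.719	5.42495	0.0692619	511.72
5.42347	455.148	449.812	5.26334	0.0722493	449.813
5.70858	400.385	395.21	5.09941	0.0752514	395.211
6.00868	352.07	347.058	4.93365	0.0782573	347.059
6.32456	309.492	304.645	4.76657	0.0812559	304.646
6.65703	271.985	267.302	4.59864	0.0842367	267.303
7.00699	238.956	234.439	4.43033	0.0871898	234.44
7.37535	209.882	205.53	4.26206	0.0901062	205.532
7.76307	184.298	180.111	4.0942	0.0929777	180.112
8.17117	161.789	157.766	3.92712	0.095797	157.768
8.60072	141.997	138.137	3.76114	0.0985572	138.139
9.05286	124.57	120.873	3.59656	0.101252	120.875
9.52877	109.218	105.681	3.43371	0.103875	105.683
10.0297	95.7455	92.3661	3.27292	0.106419	92.3685
10.1915	91.8804	88.55	3.22318	0.107196	88.5524
10.2221	245.715	242.394	3.21388	0.107341	197.579
10.5569	221.61	218.387	3.11457	0.108877	179.292
11.1119	191.903	188.832	2.95907	0.111241	156.717
11.5267	173.82	170.858	2.84982	0.112871	142.845
11.5613	238.759	235.805	2.84096	0.113001	197.259
11.6961	231.406	228.486	2.80684	0.113504	191.567
12.0817	212.007	209.18	2.71236	0.11488	176.46
12.1179	242.867	240.048	2.7037	0.115005	202.611
12.3109	233.406	230.632	2.65834	0.115657	195.228
12.9581	204.981	202.349	2.51401	0.117692	172.839
13.6393	179.794	177.3	2.3743	0.119602	152.735
14.3563	157.625	155.264	2.23957	0.12138	134.828
15.111	138.121	135.887	2.11014	0.123022	118.895
15.9054	120.952	118.841	1.98623	0.124524	104.724
16.7416	105.872	103.879	1.868	0.125885	92.1558
17.6217	92.6376	90.755	1.75549	0.127105	81.0257
18.548	81.0274	79.2505	1.64868	0.128185	71.1799
19.5231	70.8469	69.1703	1.54746	0.129128	62.4791
20.5494	61.9234	60.3418	1.45167	0.129938	54.7973
21.6297	54.1024	52.6107	1.3611	0.13062	48.0191
22.7667	47.2561	45.8493	1.27554	0.131177	42.049
23.9636	41.2634	39.937	1.19476	0.131615	36.7933
25.2233	36.0221	34.7716	1.11855	0.131938	32.1726
26.5493	31.4416	30.2628	1.0467	0.13215	28.1151
27.945	27.4229	26.3116	0.979036	0.132255	24.5391
29.4141	23.916	22.8684	0.915416	0.132257	21.4062
30.9603	20.8583	19.8704	0.855701	0.132157	18.665
32.5879	18.1926	17.2608	0.799771	0.13196	16.2676
34.3011	15.8691	14.9899	0.74751	0.131668	14.1721
36.1042	13.8443	13.0142	0.698802	0.131283	12.3414
38.0022	12.08	11.2957	0.653523	0.13081	10.7427
40	10.5431	9.8013	0.611542	0.130249	9.34732
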