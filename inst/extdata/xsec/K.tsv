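# photon mass interaction coefficients, cm^2/g
# element K  Z=19  A=39.09830 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	3873.36	3870.87	2.4688	0.0235179	3870.87
1.05257	3403.29	3400.82	2.44801	0.0253121	3400.82
1.1079	2988.5	2986.05	2.42604	0.0271995	2986.05
1.16614	2622.73	2620.3	2.40286	0.0291807	2620.3
1.22745	2299.25	2296.84	2.37845	0.0312564	2296.84
1.29198	2014.44	2012.05	2.35279	0.0334275	2012.05
1.35989	1764.1	1761.74	2.32586	0.0356951	1761.74
1.43138	1544.17	1541.84	2.29761	0.038061	1541.84
1.50663	1351.06	1348.75	2.26801	0.0405274	1348.75
1.58583	1181.2	1178.92	2.23701	0.0430971	1178.92
1.6692	1032.28	1030.03	2.20456	0.0457735	1030.03
1.75695	901.771	899.552	2.1706	0.0485601	899.553
1.84931	787.463	785.276	2.13505	0.0514608	785.277
1.94653	687.385	685.233	2.09788	0.0544788	685.233
2.04886	599.806	597.689	2.05902	0.0576168	597.689
2.15656	523.196	521.117	2.01844	0.0608764	521.117
2.26993	456.211	454.17	1.97612	0.0642574	454.171
2.38926	397.664	395.664	1.93205	0.0677577	395.664
2.51487	346.513	344.556	1.88627	0.0713731	344.556
2.64707	301.842	299.928	1.83884	0.0750968	299.929
2.78623	262.844	260.976	1.78984	0.0789194	260.976
2.9327	228.812	226.99	1.73939	0.0828291	226.991
3.08687	199.026	197.251	1.68765	0.0868118	197.252
3.24915	173.012	171.287	1.63479	0.0908508	171.287
3.41995	150.372	148.696	1.58102	0.0949277	148.697
3.59974	130.673	129.047	1.52658	0.0990223	129.048
3.60199	130.449	128.824	1.52591	0.0990723	128.825
3.61281	1243.35	1241.73	1.52271	0.0993121	1106.35
3.78897	1096.74	1095.17	1.4717	0.103113	981.317
3.98816	962.371	960.847	1.41667	0.107178	865.95
4.19782	843.81	842.337	1.36174	0.111194	763.3
4.41849	739.282	737.86	1.30721	0.115138	672.084
4.65077	647.201	645.829	1.25332	0.11899	591.133
4.89526	566.17	564.847	1.20035	0.122728	519.399
5.1526	494.899	493.624	1.14852	0.126336	455.89
5.42347	432.259	431.031	1.09804	0.129797	399.728
5.70858	377.245	376.063	1.04906	0.133099	350.116
6.00868	328.973	327.835	1.00172	0.136235	306.346
6.32456	286.656	285.561	0.956083	0.139198	267.778
6.65703	249.589	248.535	0.912183	0.141989	233.831
7.00699	217.148	216.133	0.870001	0.14461	203.986
7.37535	188.753	187.776	0.829479	0.147065	177.75
7.76307	163.938	162.998	0.790524	0.149364	154.73
8.17117	142.301	141.396	0.753023	0.151516	134.583
8.60072	123.446	122.576	0.716847	0.15353	116.965
9.05286	106.999	106.162	0.681867	0.155418	101.546
9.52877	92.6494	91.8442	0.647963	0.157189	88.0508
10.0297	80.1892	79.4153	0.615032	0.15885	76.2998
10.5569	69.3752	68.6318	0.582991	0.160408	66.0746
11.1119	59.9945	59.2808	0.551784	0.161868	57.1832
11.6961	51.861	51.1764	0.521378	0.16323	49.4569
12.3109	44.8125	44.1562	0.491764	0.164497	42.7476
12.9581	38.7071	38.0785	0.462955	0.165667	36.9253
13.6393	33.4212	32.8195	0.434979	0.166739	31.8763
14.3563	28.8471	28.2715	0.407881	0.167708	27.5007
15.111	24.8908	24.3405	0.381713	0.168573	23.7111
15.9054	21.4659	20.94	0.356533	0.169329	20.4268
16.7416	18.5009	17.9986	0.332398	0.169972	17.5807
17.6217	15.9437	15.4638	0.309363	0.1705	15.124
18.548	13.7388	13.2805	0.287473	0.17091	13.0046
19.5231	11.8385	11.4006	0.266762	0.1712	11.177
20.5494	10.2013	9.78268	0.247249	0.171371	9.6019
21.6297	8.7912	8.39084	0.228938	0.171422	8.24507
22.7667	7.57716	7.19398	0.211819	0.171355	7.07687
23.9636	6.53227	6.16523	0.195865	0.171173	6.07156
25.2233	5.63326	5.28134	0.181041	0.170879	5.20686
26.5493	4.86003	4.52225	0.1673	0.170477	4.46349
27.945	4.18912	3.86456	0.154588	0.169971	3.81876
29.4141	3.61323	3.30102	0.14285	0.169365	3.26584
30.9603	3.11964	2.81895	0.132025	0.168665	2.79247
32.5879	2.69661	2.40669	0.122055	0.167874	2.38734
34.3011	2.33407	2.0542	0.112881	0.166997	2.04072
36.1042	2.02337	1.75289	0.104444	0.166037	1.74426
38.0022	1.75709	1.4954	0.0966917	0.165	1.49078
40	1.52887	1.27541	0.089571	0.163888	1.27412
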