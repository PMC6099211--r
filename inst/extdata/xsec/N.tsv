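# photon mass interaction coefficients, cm^2/g
# element N  Z=7  A=14.00670 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	3146.55	3145.58	0.952024	0.0200914	3145.58
1.05257	2741.01	2740.04	0.944104	0.0219612	2740.04
1.1079	2386.19	2385.23	0.935479	0.0239892	2385.23
1.16614	2075.95	2075	0.926102	0.0261848	2075
1.22745	1804.89	1803.94	0.915928	0.0285572	1803.94
1.29198	1568.2	1567.27	0.904911	0.031115	1567.27
1.35989	1361.68	1360.75	0.893009	0.0338663	1360.75
1.43138	1181.59	1180.68	0.880181	0.0368182	1180.68
1.50663	1024.67	1023.76	0.866394	0.0399766	1023.76
1.58583	888.012	887.117	0.851618	0.0433455	887.117
1.6692	768.711	767.828	0.835831	0.0469276	767.829
1.75695	664.971	664.101	0.819022	0.0507227	664.102
1.84931	574.932	574.076	0.801189	0.0547286	574.077
1.94653	496.828	495.987	0.782343	0.0589398	495.987
2.04886	429.114	428.288	0.762507	0.0633477	428.288
2.15656	370.439	369.629	0.741723	0.0679404	369.629
2.26993	319.624	318.831	0.720045	0.0727024	318.832
2.38926	275.641	274.866	0.697544	0.0776147	274.866
2.51487	237.592	236.835	0.674307	0.082655	236.835
2.64707	204.693	203.955	0.650436	0.0877976	203.956
2.78623	176.264	175.545	0.626046	0.0930146	175.545
2.9327	151.709	151.01	0.601263	0.0982757	151.011
3.08687	130.462	129.782	0.576222	0.103549	129.783
3.24915	112.109	111.449	0.55106	0.108803	111.45
3.41995	96.302	95.6621	0.525918	0.114005	95.6631
3.59974	82.6932	82.0732	0.500932	0.119125	82.0742
3.78897	70.9824	70.382	0.476233	0.124134	70.3831
3.98816	60.9092	60.3283	0.451944	0.129004	60.3295
4.19782	52.2486	51.6867	0.428172	0.133713	51.688
4.41849	44.8057	44.2624	0.405017	0.138241	44.2639
4.65077	38.4121	37.887	0.382559	0.14257	37.8886
4.89526	32.9224	32.4149	0.36087	0.146687	32.4165
5.1526	28.2108	27.7202	0.340003	0.150582	27.722
5.42347	24.1688	23.6946	0.320004	0.154247	23.6965
5.70858	20.7027	20.2441	0.300903	0.157676	20.2462
6.00868	17.7317	17.2881	0.28272	0.160868	17.2903
6.32456	15.1862	14.7569	0.265467	0.163823	14.7592
6.65703	13.0061	12.5904	0.249145	0.166541	12.5929
7.00699	11.1398	10.7371	0.233743	0.169028	10.7396
7.37535	9.54278	9.15225	0.219243	0.171288	9.15499
7.76307	8.17612	7.79717	0.20562	0.173329	7.80006
8.17117	7.00777	6.63977	0.192838	0.17516	6.64282
8.60072	6.00975	5.65211	0.180854	0.176791	5.65531
9.05286	5.15527	4.80741	0.169621	0.178235	4.81078
9.52877	4.4227	4.08411	0.15909	0.179501	4.08766
10.0297	3.79866	3.46885	0.149208	0.180602	3.47258
10.5569	3.26709	2.94562	0.139924	0.18155	2.94953
11.1119	2.81428	2.50074	0.131188	0.182354	2.50484
11.6961	2.42855	2.12257	0.122956	0.183026	2.12687
12.3109	2.09994	1.80118	0.115186	0.183573	1.80569
12.9581	1.81995	1.5281	0.107842	0.184003	1.53282
13.6393	1.58135	1.29614	0.100893	0.184323	1.30108
14.3563	1.37798	1.09913	0.0943115	0.184539	1.10431
15.111	1.20459	0.931863	0.0880738	0.184655	0.937276
15.9054	1.05671	0.789871	0.0821605	0.184676	0.795531
16.7416	0.930523	0.669364	0.0765547	0.184605	0.675281
17.6217	0.822801	0.567113	0.0712426	0.184445	0.573297
18.548	0.730785	0.480374	0.0662122	0.184198	0.486834
19.5231	0.65213	0.40681	0.0614535	0.183867	0.413554
20.5494	0.584844	0.344434	0.0569575	0.183453	0.351472
21.6297	0.52723	0.291556	0.0527162	0.182958	0.298897
22.7667	0.477846	0.24674	0.048722	0.182384	0.254393
23.9636	0.435466	0.208766	0.0449671	0.181732	0.216741
25.2233	0.399045	0.176596	0.0414434	0.181005	0.184902
26.5493	0.367697	0.14935	0.0381426	0.180204	0.157995
27.945	0.340484	0.126098	0.0350557	0.17933	0.13509
29.4141	0.316998	0.106438	0.0321735	0.178386	0.115788
30.9603	0.296699	0.089838	0.0294866	0.177374	0.0995525
32.5879	0.279103	0.0758215	0.0269864	0.176295	0.0859092
34.3011	0.263804	0.0639875	0.0246652	0.175152	0.0744562
36.1042	0.250458	0.0539968	0.0225169	0.173945	0.0648542
38.0022	0.238776	0.0455629	0.0205386	0.172675	0.0568159
40	0.228517	0.0384437	0.0187303	0.171343	0.0500989
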