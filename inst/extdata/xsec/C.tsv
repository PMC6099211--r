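# photon mass interaction coefficients, cm^2/g
# element C  Z=6  A=12.01070 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	2057.86	2057.03	0.795733	0.0258127	2057.03
1.05257	1787.29	1786.47	0.787165	0.0281709	1786.47
1.1079	1551.29	1550.48	0.777896	0.0307115	1550.48
1.16614	1344.84	1344.04	0.76789	0.0334421	1344.04
1.22745	1164.64	1163.85	0.757115	0.0363693	1163.85
1.29198	1008.06	1007.27	0.745545	0.0394986	1007.27
1.35989	872.062	871.286	0.733155	0.0428339	871.286
1.43138	754.018	753.251	0.719931	0.0463772	753.252
1.50663	651.611	650.855	0.705862	0.0501282	650.855
1.58583	562.819	562.074	0.690948	0.0540845	562.074
1.6692	485.874	485.141	0.6752	0.0582406	485.141
1.75695	419.232	418.511	0.658637	0.0625883	418.511
1.84931	361.545	360.836	0.641292	0.067116	360.837
1.94653	311.636	310.941	0.62321	0.071809	310.942
2.04886	268.482	267.801	0.604447	0.0766495	267.801
2.15656	231.187	230.52	0.585072	0.0816163	230.521
2.26993	198.974	198.322	0.565167	0.0866856	198.323
2.38926	171.165	170.529	0.544822	0.0918312	170.529
2.51487	147.172	146.551	0.524137	0.0970247	146.552
2.64707	126.482	125.876	0.503218	0.102237	125.877
2.78623	108.649	108.06	0.482176	0.107436	108.061
2.9327	93.2883	92.7146	0.461123	0.112594	92.7154
3.08687	80.0426	79.4847	0.440172	0.117679	79.4856
3.24915	68.6381	68.096	0.41943	0.122664	68.0969
3.41995	58.8386	58.3121	0.399001	0.127521	58.3132
3.59974	50.4222	49.911	0.378982	0.132226	49.9121
3.78897	43.1967	42.7005	0.359458	0.136758	42.7017
3.98816	36.9964	36.5148	0.340508	0.141099	36.5162
4.19782	31.6782	31.2108	0.322195	0.145232	31.2122
4.41849	27.1187	26.6649	0.304574	0.149146	26.6665
4.65077	23.2112	22.7707	0.287685	0.152832	22.7723
4.89526	19.864	19.4361	0.271557	0.156284	19.4379
5.1526	16.998	16.5823	0.256206	0.159502	16.5841
5.42347	14.5423	14.1382	0.241637	0.162484	14.1402
5.70858	12.4383	12.0452	0.227843	0.165235	12.0473
6.00868	10.6412	10.2586	0.21481	0.167761	10.2608
6.32456	9.10651	8.73393	0.202514	0.170069	8.73627
6.65703	7.7964	7.4333	0.190925	0.172168	7.43578
7.00699	6.67825	6.32418	0.180008	0.174069	6.32679
7.37535	5.72419	5.37868	0.169725	0.175782	5.38144
7.76307	4.91032	4.57297	0.160036	0.177318	4.57586
8.17117	4.21619	3.8866	0.1509	0.178688	3.88965
8.60072	3.62429	3.30211	0.142275	0.179904	3.30532
9.05286	3.11826	2.80316	0.134122	0.180976	2.80653
9.52877	2.68496	2.37664	0.126402	0.181914	2.38018
10.0297	2.31645	2.01464	0.119079	0.182727	2.01835
10.5569	2.00299	1.70745	0.112119	0.183424	1.71135
11.1119	1.73633	1.44682	0.105492	0.184012	1.45091
11.6961	1.50941	1.22574	0.0991706	0.184497	1.23003
12.3109	1.31627	1.03825	0.0931328	0.184886	1.04274
12.9581	1.15181	0.879264	0.0873597	0.185183	0.88397
13.6393	1.01171	0.744482	0.0818361	0.185391	0.749413
14.3563	0.892304	0.630241	0.0765506	0.185512	0.635404
15.111	0.790474	0.533428	0.0714951	0.18555	0.538832
15.9054	0.703571	0.4514	0.0666644	0.185506	0.457055
16.7416	0.629348	0.381914	0.0620555	0.185379	0.387828
17.6217	0.565901	0.323061	0.0576674	0.185172	0.329245
18.548	0.511609	0.273226	0.0535002	0.184883	0.279687
19.5231	0.465101	0.231034	0.0495547	0.184513	0.237782
20.5494	0.425213	0.19532	0.0458312	0.184061	0.202364
21.6297	0.390955	0.165096	0.0423293	0.18353	0.172444
22.7667	0.361487	0.139521	0.0390476	0.182918	0.147183
23.9636	0.336096	0.117886	0.0359826	0.182227	0.12587
25.2233	0.314175	0.0995868	0.0331292	0.181459	0.107901
26.5493	0.295208	0.084112	0.0304805	0.180616	0.0927652
27.945	0.278633	0.0709072	0.028028	0.179698	0.0799074
29.4141	0.264233	0.059762	0.0257621	0.178709	0.0691173
30.9603	0.251692	0.0503684	0.0236721	0.177651	0.0600868
32.5879	0.240725	0.0424511	0.0217471	0.176527	0.0525403
34.3011	0.231093	0.0357782	0.0199762	0.175338	0.0462458
36.1042	0.222591	0.0301541	0.0183485	0.174088	0.0410075
38.0022	0.215046	0.025414	0.0168535	0.172779	0.0366602
40	0.208313	0.0214189	0.0154814	0.171412	0.0330648
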