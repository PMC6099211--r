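# photon mass interaction coefficients, cm^2/g
# element Be  Z=4  A=9.01218 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	545.226	544.751	0.436297	0.0380268	544.751
1.05257	469.586	469.116	0.42876	0.0411248	469.116
1.1079	404.227	403.762	0.420767	0.0443948	403.762
1.16614	347.783	347.323	0.412322	0.0478324	347.323
1.22745	299.065	298.61	0.403436	0.0514313	298.611
1.29198	257.039	256.59	0.394126	0.0551821	256.59
1.35989	220.806	220.362	0.384414	0.059073	220.363
1.43138	189.584	189.147	0.374333	0.0630891	189.147
1.50663	162.695	162.264	0.363919	0.0672133	162.265
1.58583	139.551	139.127	0.353216	0.0714257	139.127
1.6692	119.641	119.223	0.342272	0.0757044	119.224
1.75695	102.523	102.112	0.331144	0.0800257	102.112
1.84931	87.8125	87.4082	0.319888	0.0843649	87.4086
1.94653	75.1785	74.7812	0.308566	0.0886963	74.7816
2.04886	64.3337	63.9434	0.297239	0.0929942	63.9439
2.15656	55.0156	54.6324	0.285968	0.0972337	54.6329
2.26993	47.0265	46.6503	0.274814	0.101391	46.6508
2.38926	40.1868	39.8175	0.263832	0.105443	39.8181
2.51487	34.3336	33.9711	0.253074	0.10937	33.9718
2.64707	29.3266	28.9709	0.242587	0.113155	28.9716
2.78623	25.0453	24.6961	0.23241	0.116782	24.6969
2.9327	21.386	21.0432	0.222576	0.120239	21.0441
3.08687	18.2432	17.9066	0.213111	0.123519	17.9075
3.24915	15.5524	15.2218	0.20403	0.126616	15.2227
3.41995	13.261	12.9362	0.195344	0.129528	12.9372
3.59974	11.3101	10.9908	0.187051	0.132256	10.9919
3.78897	9.64953	9.33558	0.179144	0.134806	9.33673
3.98816	8.23581	7.92702	0.171608	0.137184	7.92824
4.19782	7.033	6.72918	0.16442	0.139401	6.73047
4.41849	6.00992	5.71089	0.157555	0.141467	5.71227
4.65077	5.13985	4.84548	0.150983	0.143395	4.84693
4.89526	4.40003	4.11017	0.144671	0.145198	4.1117
5.1526	3.77104	3.48556	0.138589	0.146889	3.48718
5.42347	3.23631	2.95513	0.132708	0.148479	2.95684
5.70858	2.78176	2.50478	0.127	0.149978	2.50659
6.00868	2.39537	2.12253	0.121443	0.151396	2.12444
6.32456	2.06692	1.79816	0.116016	0.15274	1.80018
6.65703	1.7877	1.52298	0.110704	0.154016	1.52511
7.00699	1.5503	1.28958	0.105496	0.155228	1.29183
7.37535	1.34844	1.09168	0.100382	0.15638	1.09405
7.76307	1.17674	0.923909	0.0953577	0.157472	0.926413
8.17117	1.03066	0.781728	0.090422	0.158506	0.784368
8.60072	0.906316	0.66126	0.0855765	0.15948	0.664044
9.05286	0.800236	0.559018	0.0808258	0.160393	0.561952
9.52877	0.70958	0.472161	0.0761772	0.161241	0.475253
10.0297	0.632403	0.39874	0.0716403	0.162023	0.401996
10.5569	0.566643	0.336684	0.067226	0.162733	0.340112
11.1119	0.510557	0.284243	0.0629462	0.163368	0.28785
11.6961	0.462669	0.239933	0.0588131	0.163923	0.243727
12.3109	0.421734	0.202501	0.0548382	0.164395	0.206487
12.9581	0.386694	0.170882	0.0510317	0.164781	0.175068
13.6393	0.356658	0.144178	0.0474021	0.165078	0.148572
14.3563	0.330869	0.121629	0.0439556	0.165284	0.126237
15.111	0.308686	0.102591	0.0406957	0.165399	0.10742
15.9054	0.289566	0.0865199	0.0376235	0.165422	0.0915763
16.7416	0.273048	0.0729552	0.0347375	0.165355	0.0782465
17.6217	0.258742	0.0615079	0.0320343	0.165199	0.0670409
18.548	0.246314	0.051849	0.0295084	0.164957	0.0576306
19.5231	0.235483	0.0437002	0.0271534	0.16463	0.0497376
20.5494	0.22601	0.0368266	0.0249617	0.164222	0.0431268
21.6297	0.217689	0.0310294	0.0229255	0.163735	0.0375996
22.7667	0.210349	0.0261408	0.0210367	0.163172	0.0329883
23.9636	0.203842	0.0220191	0.0192872	0.162536	0.0291512
25.2233	0.198043	0.0185445	0.017669	0.16183	0.0259684
26.5493	0.192846	0.0156158	0.0161742	0.161056	0.0233389
27.945	0.188146	0.0131339	0.0147952	0.160217	0.0211634
29.4141	0.183885	0.0110455	0.0135246	0.159315	0.0193887
30.9603	0.179998	0.00928972	0.0123551	0.158353	0.0179537
32.5879	0.176426	0.00781342	0.0112798	0.157333	0.0168052
34.3011	0.173121	0.00657208	0.0102922	0.156257	0.0158987
36.1042	0.170041	0.00552824	0.00938576	0.155127	0.0151963
38.0022	0.167151	0.00465045	0.00855465	0.153946	0.0146665
40	0.16442	0.00391224	0.00779326	0.152715	0.0142824
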