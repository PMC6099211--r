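# photon mass interaction coefficients, cm^2/g
# element Li  Z=3  A=6.94100 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	207.266	206.917	0.302817	0.0461285	206.917
1.05257	177.446	177.1	0.296943	0.0493254	177.1
1.1079	151.725	151.382	0.290859	0.0526174	151.382
1.16614	129.691	129.35	0.28459	0.0559896	129.35
1.22745	110.821	110.483	0.278165	0.059425	110.483
1.29198	94.6674	94.3329	0.271612	0.0629054	94.3331
1.35989	80.8446	80.5132	0.264967	0.0664114	80.5134
1.43138	69.0205	68.6923	0.258263	0.0699231	68.6926
1.50663	58.91	58.585	0.251535	0.0734204	58.5853
1.58583	50.2678	49.9461	0.244818	0.0768841	49.9464
1.6692	42.8836	42.5652	0.238145	0.080296	42.5655
1.75695	36.5765	36.2613	0.231546	0.0836398	36.2617
1.84931	31.1915	30.8795	0.225047	0.0869012	30.8799
1.94653	26.5953	26.2866	0.21867	0.0900687	26.287
2.04886	22.674	22.3684	0.212433	0.0931337	22.3689
2.15656	19.3296	19.0271	0.206347	0.0960904	19.0276
2.26993	16.4782	16.1789	0.200419	0.0989362	16.1794
2.38926	14.0481	13.7518	0.194649	0.101672	13.7524
2.51487	11.9778	11.6844	0.189033	0.1043	11.6851
2.64707	10.2145	9.92416	0.183562	0.106826	9.92481
2.78623	8.71339	8.42591	0.178223	0.109258	8.42661
2.9327	7.43579	7.15119	0.172999	0.111605	7.15193
3.08687	6.342	6.06025	0.16787	0.113879	6.06104
3.24915	5.40893	5.13002	0.162817	0.116089	5.13087
3.41995	4.61787	4.34181	0.157818	0.118247	4.34271
3.59974	3.94726	3.67405	0.152852	0.120365	3.675
3.78897	3.37878	3.10843	0.147901	0.12245	3.10945
3.98816	2.89688	2.62942	0.142948	0.124512	2.6305
4.19782	2.48836	2.22382	0.13798	0.126557	2.22498
4.41849	2.14204	1.88046	0.132986	0.12859	1.88169
4.65077	1.8484	1.58983	0.127961	0.130613	1.59114
4.89526	1.5994	1.34387	0.122901	0.132628	1.34527
5.1526	1.38821	1.13577	0.117808	0.134631	1.13725
5.42347	1.20902	0.959715	0.112688	0.136621	0.961295
5.70858	1.05695	0.810808	0.107549	0.138592	0.81249
6.00868	0.927824	0.684882	0.102404	0.140538	0.686672
6.32456	0.818128	0.578411	0.0972686	0.142449	0.580315
6.65703	0.724883	0.488404	0.0921622	0.144316	0.490429
7.00699	0.645564	0.41233	0.0871057	0.146129	0.414481
7.37535	0.57804	0.348043	0.0821217	0.147876	0.350326
7.76307	0.520505	0.293727	0.0772331	0.149546	0.296148
8.17117	0.471433	0.247843	0.0724627	0.151128	0.250409
8.60072	0.429534	0.209089	0.0678319	0.152613	0.211806
9.05286	0.393549	0.176198	0.0633598	0.153991	0.179071
9.52877	0.362521	0.148202	0.0590627	0.155256	0.151238
10.0297	0.336024	0.124668	0.0549533	0.156402	0.127872
10.5569	0.31335	0.104883	0.0510408	0.157426	0.10826
11.1119	0.293904	0.0882472	0.0473306	0.158326	0.0918032
11.6961	0.277185	0.074258	0.0438249	0.159102	0.0779986
12.3109	0.26277	0.0624932	0.0405226	0.159754	0.0664239
12.9581	0.250304	0.052598	0.0374205	0.160286	0.0567246
13.6393	0.239488	0.0442744	0.0345133	0.1607	0.0486027
14.3563	0.230067	0.037272	0.0317947	0.161	0.041808
15.111	0.221828	0.0313805	0.0292575	0.16119	0.0361302
15.9054	0.214591	0.0264231	0.026894	0.161274	0.0313928
16.7416	0.208203	0.0222513	0.0246965	0.161256	0.0274473
17.6217	0.202536	0.0187402	0.0226569	0.161139	0.024169
18.548	0.197481	0.0157848	0.0207673	0.160929	0.0214531
19.5231	0.192945	0.0132969	0.0190195	0.160628	0.0192115
20.5494	0.188849	0.0112024	0.0174054	0.160242	0.0173702
21.6297	0.185128	0.00943877	0.0159168	0.159772	0.0158667
22.7667	0.181724	0.00795368	0.0145457	0.159225	0.0146489
23.9636	0.178589	0.00670298	0.0132842	0.158602	0.0136727
25.2233	0.175682	0.00564982	0.0121246	0.157908	0.0129013
26.5493	0.172968	0.00476231	0.0110597	0.157146	0.0123027
27.945	0.170414	0.00401339	0.0100826	0.156318	0.01185
29.4141	0.167997	0.00338155	0.00918687	0.155428	0.0115216
30.9603	0.165694	0.0028486	0.00836646	0.154479	0.0112993
32.5879	0.163487	0.00239915	0.00761569	0.153472	0.0111674
34.3011	0.16136	0.00202021	0.00692924	0.15241	0.011113
36.1042	0.159299	0.00170077	0.00630214	0.151296	0.0111248
38.0022	0.157293	0.00143154	0.00572975	0.150132	0.0111932
40	0.155331	0.00120469	0.00520775	0.148919	0.0113102
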