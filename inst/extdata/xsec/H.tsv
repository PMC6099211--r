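# photon mass interaction coefficients, cm^2/g
# element H  Z=1  A=1.00794 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	0.313827	0	0.264532	0.0492945	0.000133011
1.05257	0.315646	0	0.261745	0.0539009	0.000152881
1.1079	0.317601	0	0.258719	0.0588826	0.000175531
1.16614	0.319697	0	0.255438	0.0642592	0.000201304
1.22745	0.321939	0	0.25189	0.070049	0.000230571
1.29198	0.324331	0	0.248062	0.0762687	0.000263731
1.35989	0.326875	0	0.243942	0.0829327	0.000301213
1.43138	0.329572	0	0.23952	0.0900522	0.000343473
1.50663	0.332422	0	0.234787	0.097635	0.000390989
1.58583	0.335424	0	0.22974	0.105684	0.000444255
1.6692	0.338572	0	0.224374	0.114198	0.000503779
1.75695	0.341859	0	0.218691	0.123169	0.000570071
1.84931	0.345278	0	0.212696	0.132581	0.000643637
1.94653	0.348814	0	0.206399	0.142415	0.000724966
2.04886	0.352453	0	0.199814	0.152639	0.000814519
2.15656	0.356178	0	0.19296	0.163218	0.000912716
2.26993	0.359968	0	0.185861	0.174106	0.00101992
2.38926	0.363799	0	0.178548	0.185251	0.00113644
2.51487	0.367647	0	0.171054	0.196593	0.0012625
2.64707	0.371484	0	0.163419	0.208065	0.00139823
2.78623	0.375282	0	0.155684	0.219598	0.00154368
2.9327	0.379012	0	0.147895	0.231117	0.0016988
3.08687	0.382645	0	0.140099	0.242546	0.00186347
3.24915	0.386153	0	0.132344	0.253809	0.00203745
3.41995	0.38951	0	0.124677	0.264833	0.00222045
3.59974	0.392691	0	0.117142	0.275548	0.00241214
3.78897	0.395674	0	0.109783	0.285891	0.00261211
3.98816	0.398441	0	0.102636	0.295805	0.00281999
4.19782	0.400979	0	0.095735	0.305244	0.0030354
4.41849	0.403275	0	0.0891071	0.314168	0.00325798
4.65077	0.405323	0	0.0827738	0.32255	0.00348746
4.89526	0.407121	0	0.0767504	0.33037	0.0037236
5.1526	0.408666	0	0.0710468	0.33762	0.0039663
5.42347	0.409964	0	0.0656674	0.344296	0.00421551
5.70858	0.411018	0	0.0606118	0.350406	0.0044713
6.00868	0.411835	0	0.0558757	0.35596	0.00473382
6.32456	0.412426	0	0.0514512	0.360975	0.00500333
6.65703	0.412799	0	0.0473277	0.365471	0.00528017
7.00699	0.412964	0	0.0434928	0.369472	0.00556475
7.37535	0.412934	0	0.0399324	0.373001	0.00585753
7.76307	0.412717	0	0.0366319	0.376085	0.00615906
8.17117	0.412326	0	0.0335761	0.37875	0.00646988
8.60072	0.411769	0	0.0307501	0.381019	0.00679057
9.05286	0.411056	0	0.0281394	0.382916	0.00712172
9.52877	0.410196	0	0.02573	0.384466	0.00746392
10.0297	0.409197	0	0.0235086	0.385689	0.00781774
10.5569	0.408067	0	0.0214626	0.386605	0.00818376
11.1119	0.406813	0	0.0195802	0.387233	0.0085625
11.6961	0.40544	0	0.0178501	0.38759	0.00895451
12.3109	0.403955	0	0.0162617	0.387694	0.00936029
12.9581	0.402364	0	0.0148049	0.387559	0.00978034
13.6393	0.40067	0	0.0134702	0.3872	0.0102151
14.3563	0.398879	0	0.0122485	0.386631	0.0106651
15.111	0.396995	0	0.0111314	0.385863	0.0111307
15.9054	0.395021	0	0.0101108	0.38491	0.0116123
16.7416	0.39296	0	0.00917916	0.383781	0.0121102
17.6217	0.390817	0	0.00832948	0.382487	0.0126249
18.548	0.388592	0	0.00755514	0.381037	0.0131566
19.5231	0.386289	0	0.00685002	0.379439	0.0137055
20.5494	0.383909	0	0.00620837	0.377701	0.0142718
21.6297	0.381455	0	0.00562489	0.37583	0.0148559
22.7667	0.378928	0	0.00509463	0.373834	0.0154576
23.9636	0.37633	0	0.00461304	0.371716	0.0160772
25.2233	0.37366	0	0.00417587	0.369484	0.0167145
26.5493	0.370922	0	0.00377924	0.367143	0.0173697
27.945	0.368115	0	0.00341957	0.364695	0.0180424
29.4141	0.36524	0	0.00309355	0.362146	0.0187327
30.9603	0.362297	0	0.00279816	0.359499	0.01944
32.5879	0.359289	0	0.00253062	0.356758	0.0201643
34.3011	0.356214	0	0.00228839	0.353926	0.0209049
36.1042	0.353074	0	0.00206916	0.351005	0.0216614
38.0022	0.349869	0	0.0018708	0.347998	0.0224332
40	0.3466	0	0.00169139	0.344908	0.0232196
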