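# photon mass interaction coefficients, cm^2/g
# element Mg  Z=12  A=24.30500 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	831.662	830.054	1.5843	0.023876	830.054
1.05257	725.859	724.264	1.56993	0.0258456	724.264
1.1079	633.388	631.806	1.55459	0.0279384	631.806
1.16614	552.58	551.011	1.53828	0.0301545	551.012
1.22745	481.974	480.42	1.52098	0.0324928	480.42
1.29198	420.292	418.754	1.50271	0.0349505	418.754
1.35989	5180.46	5178.94	1.48348	0.0375233	5178.94
1.43138	4597.4	4595.9	1.46333	0.0402053	4595.9
1.50663	4028.56	4027.08	1.4423	0.0429893	4027.08
1.58583	3529.53	3528.06	1.42045	0.0458661	3528.06
1.6692	3091.81	3090.36	1.39783	0.0488258	3090.36
1.75695	2713.38	2711.95	1.37452	0.0518572	2711.95
1.84931	2381.6	2380.19	1.35059	0.0549488	2380.19
1.94653	2088.44	2087.05	1.32613	0.0580888	2087.05
2.04886	1829.66	1828.29	1.30121	0.0612662	1828.29
2.15656	1601.45	1600.1	1.27589	0.0644708	1600.11
2.26993	1400.39	1399.07	1.25024	0.0676941	1399.07
2.38926	1223.43	1222.14	1.22429	0.0709298	1222.14
2.51487	1067.84	1066.56	1.19807	0.0741742	1066.56
2.64707	931.094	929.845	1.17158	0.077426	929.845
2.78623	811.064	809.839	1.14482	0.0806868	809.839
2.9327	705.995	704.794	1.11773	0.0839606	704.794
3.08687	613.772	612.595	1.09027	0.087253	612.596
3.24915	533.053	531.9	1.06239	0.0905711	531.9
3.41995	462.685	461.557	1.03401	0.0939219	461.557
3.59974	401.378	400.275	1.00508	0.0973122	400.276
3.78897	347.997	346.921	0.975555	0.100747	346.922
3.98816	301.546	300.497	0.945393	0.104229	300.498
4.19782	261.15	260.127	0.914583	0.107759	260.129
4.41849	226.039	225.045	0.883135	0.111333	225.046
4.65077	195.542	194.576	0.851084	0.114946	194.577
4.89526	169.067	168.129	0.818489	0.118589	168.131
5.1526	146.097	145.189	0.785433	0.12225	145.191
5.42347	126.181	125.303	0.75202	0.125914	125.304
5.70858	108.911	108.063	0.718377	0.129565	108.064
6.00868	93.9194	93.1016	0.684643	0.133185	93.1034
6.32456	80.961	80.1733	0.650971	0.136752	80.1752
6.65703	69.7648	69.007	0.617523	0.140248	69.0091
7.00699	60.0955	59.3674	0.584461	0.143652	59.3697
7.37535	51.7486	51.0498	0.551947	0.146945	51.0522
7.76307	44.5465	43.8762	0.520134	0.150108	43.8788
8.17117	38.3348	37.6925	0.489164	0.153124	37.6953
8.60072	32.9798	32.3647	0.459164	0.15598	32.3676
9.05286	28.3539	27.765	0.430244	0.158662	27.7682
9.52877	24.3534	23.7898	0.402493	0.161163	23.7931
10.0297	20.9156	20.3761	0.375977	0.163475	20.3796
10.5569	17.9623	17.4459	0.350747	0.165593	17.4497
11.1119	15.426	14.9316	0.326828	0.167517	14.9355
11.6961	13.2484	12.7749	0.30423	0.169246	12.7791
12.3109	11.3795	10.9257	0.282946	0.170783	10.9301
12.9581	9.77585	9.34076	0.262955	0.172132	9.34534
13.6393	8.40027	7.98275	0.24422	0.173299	7.98757
14.3563	7.22063	6.81964	0.226698	0.174289	6.8247
15.111	6.20929	5.82384	0.210336	0.17511	5.82915
15.9054	5.34244	4.9716	0.195075	0.17577	4.97716
16.7416	4.59962	4.24249	0.180854	0.176277	4.24831
17.6217	3.96321	3.61896	0.167608	0.176638	3.62505
18.548	3.41806	3.08592	0.155275	0.176862	3.09229
19.5231	2.95116	2.63041	0.143795	0.176955	2.63706
20.5494	2.55134	2.24131	0.13311	0.176925	2.24824
21.6297	2.20899	1.90904	0.123169	0.176778	1.91628
22.7667	1.91587	1.62543	0.113922	0.17652	1.63297
23.9636	1.66491	1.38343	0.105328	0.176155	1.39129
25.2233	1.45006	1.17702	0.0973474	0.175689	1.1852
26.5493	1.2661	1.00103	0.0899439	0.175126	1.00955
27.945	1.10859	0.851037	0.083085	0.17447	0.859893
29.4141	0.973749	0.723285	0.0767399	0.173724	0.732491
30.9603	0.858288	0.614516	0.0708792	0.172892	0.624079
32.5879	0.759391	0.521939	0.065475	0.171978	0.531866
34.3011	0.674652	0.443167	0.0605002	0.170984	0.453468
36.1042	0.602008	0.376165	0.0559282	0.169914	0.386845
38.0022	0.539697	0.319192	0.0517334	0.168772	0.330259
40	0.486211	0.270761	0.0478905	0.167559	0.282222
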