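# photon mass interaction coefficients, cm^2/g
# element O  Z=8  A=15.99940 g/mol
E_keV	mu_rho	mu_rho_pe	mu_rho_coh	mu_rho_incoh	muen_rho
1	4387.03	4385.91	1.10736	0.0160572	4385.91
1.05257	3837.33	3836.21	1.09989	0.0176025	3836.21
1.1079	3354.09	3352.98	1.09173	0.0192834	3352.98
1.16614	2929.6	2928.5	1.08283	0.0211092	2928.5
1.22745	2557	2555.9	1.07314	0.0230891	2555.9
1.29198	2230.18	2229.09	1.0626	0.0252323	2229.09
1.35989	1943.74	1942.66	1.05117	0.0275477	1942.66
1.43138	1692.87	1691.8	1.03879	0.030044	1691.8
1.50663	1473.33	1472.27	1.02542	0.0327289	1472.27
1.58583	1281.34	1280.29	1.01101	0.0356096	1280.29
1.6692	1113.57	1112.54	0.99551	0.0386919	1112.54
1.75695	967.084	966.063	0.978898	0.0419804	966.063
1.84931	839.268	838.262	0.961144	0.0454778	838.262
1.94653	727.83	726.838	0.942231	0.0491849	726.838
2.04886	630.742	629.766	0.922153	0.0531	629.767
2.15656	546.14	545.182	0.900916	0.0572188	545.182
2.26993	472.411	471.471	0.878542	0.0615342	471.472
2.38926	408.421	407.5	0.855068	0.0660359	407.5
2.51487	352.914	352.013	0.830546	0.0707105	352.014
2.64707	304.793	303.912	0.805047	0.0755412	303.913
2.78623	263.098	262.239	0.778658	0.0805081	262.239
2.9327	226.991	226.153	0.751483	0.0855884	226.154
3.08687	195.652	194.838	0.72364	0.0907564	194.839
3.24915	168.507	167.716	0.69526	0.0959843	167.717
3.41995	145.067	144.299	0.666488	0.101242	144.3
3.59974	124.837	124.093	0.637474	0.1065	124.094
3.78897	107.385	106.665	0.608374	0.111726	106.666
3.98816	92.3371	91.6408	0.579346	0.116889	91.642
4.19782	79.3676	78.6951	0.550545	0.121959	78.6963
4.41849	68.1948	67.5458	0.522122	0.126908	67.5471
4.65077	58.5741	57.9482	0.494218	0.131708	57.9497
4.89526	50.2938	49.6905	0.466964	0.136336	49.6921
5.1526	43.1703	42.5891	0.440475	0.140771	42.5908
5.42347	37.0448	36.485	0.414851	0.144996	36.4868
5.70858	31.7799	31.2407	0.390174	0.148996	31.2427
6.00868	27.2567	26.7374	0.36651	0.152761	26.7395
6.32456	23.3724	22.8722	0.343905	0.156285	22.8745
6.65703	20.0383	19.5564	0.322386	0.159564	19.5588
7.00699	17.1777	16.7132	0.301968	0.162599	16.7157
7.37535	14.7245	14.2764	0.282647	0.16539	14.2791
7.76307	12.6215	12.1891	0.264411	0.167943	12.192
8.17117	10.8194	10.4019	0.247236	0.170265	10.4049
8.60072	9.27597	8.87251	0.231089	0.172362	8.8757
9.05286	7.95418	7.564	0.215933	0.174243	7.56736
9.52877	6.82296	6.44532	0.201727	0.175917	6.44885
10.0297	5.85545	5.48963	0.188423	0.177395	5.49335
10.5569	5.02434	4.66968	0.175974	0.178686	4.67358
11.1119	4.31525	3.97112	0.164329	0.1798	3.97522
11.6961	3.71037	3.37618	0.153437	0.180748	3.38049
12.3109	3.19444	2.86965	0.143246	0.181539	2.87416
12.9581	2.75439	2.4385	0.133705	0.182183	2.44323
13.6393	2.37906	2.07161	0.124765	0.18269	2.07656
14.3563	2.05892	1.75947	0.116378	0.183068	1.76465
15.111	1.78582	1.49399	0.108502	0.183326	1.49941
15.9054	1.55281	1.26825	0.101097	0.183469	1.27391
16.7416	1.35398	1.07634	0.0941298	0.183505	1.08226
17.6217	1.18425	0.913243	0.0875684	0.18344	0.919432
18.548	1.03933	0.774664	0.0813867	0.183277	0.781127
19.5231	0.91553	0.656947	0.0755621	0.18302	0.663694
20.5494	0.809728	0.556978	0.0700752	0.182674	0.564017
21.6297	0.719254	0.472103	0.0649096	0.182242	0.479443
22.7667	0.641835	0.40006	0.0600513	0.181724	0.407711
23.9636	0.575539	0.338925	0.0554885	0.181125	0.346897
25.2233	0.518716	0.28706	0.0512105	0.180446	0.295361
26.5493	0.469967	0.24307	0.0472077	0.179689	0.25171
27.945	0.427788	0.205462	0.043471	0.178855	0.214449
29.4141	0.391561	0.173623	0.0399911	0.177947	0.182966
30.9603	0.36043	0.146705	0.0367583	0.176966	0.156413
32.5879	0.333626	0.12395	0.0337624	0.175914	0.13403
34.3011	0.310501	0.104715	0.0309924	0.174794	0.115175
36.1042	0.2905	0.0884565	0.0284366	0.173607	0.0993044
38.0022	0.273155	0.074716	0.0260828	0.172356	0.0859589
40	0.258066	0.0631043	0.0239185	0.171043	0.0747489
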