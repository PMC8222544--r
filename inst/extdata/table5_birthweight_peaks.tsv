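rt	mz	p_value	max_peak_height	passed_th4_60pct	passed_th3_10k_2pct
3.664	549.1632	3.12E-12	3703	No	No
3.663	487.1944	2.25E-11	5983	No	No
3.665	518.1235	9.11E-11	1624	No	No
5.566	416.3373	1.52E-10	4241	No	No
5.751	412.3035	1.62E-10	11160	Yes	No
8.868	402.7667	3.32E-10	17350	Yes	Yes
8.866	788.5606	3.61E-10	14002	Yes	Yes
3.655	482.2388	3.88E-10	34862	Yes	Yes
3.662	429.1907	8.25E-10	3790	No	No
4.834	289.2162	8.61E-10	11937	Yes	No
9.05	766.5737	1.25E-09	5761	Yes	No
4.704	351.5335	2.27E-09	1564	No	No
8.87	394.7769	2.81E-09	3892	No	No
4.703	326.5377	4.22E-09	1922	No	No
5.702	456.3321	4.23E-09	2804	No	No
4.225	390.2097	4.75E-09	8354	No	No
8.399	407.766	5.07E-09	2780	No	No
8.402	776.5789	5.25E-09	3936	No	No
5.796	367.157	5.64E-09	4124	No	No
0.613	144.1254	6.27E-09	11772	Yes	No
0.813	287.2451	8.31E-09	2335	No	No
0.599	390.3455	8.39E-09	6976	No	No
8.961	386.7638	8.64E-09	21069	Yes	Yes
8.863	766.5765	9.28E-09	60338	Yes	Yes
9.078	385.3477	1.10E-08	50276	Yes	Yes
4.704	567.123	1.32E-08	8785	No	No
4.704	582.0884	1.43E-08	10873	Yes	No
8.961	756.5529	1.65E-08	12703	Yes	No
4.705	342.5484	1.81E-08	3836	No	No
5.648	463.2338	1.84E-08	15180	Yes	Yes
4.846	475.1308	2.74E-08	2328	No	No
5.307	464.6273	2.91E-08	1382	No	No
3.828	274.0564	3.24E-08	2644	No	No
8.962	734.571	3.95E-08	44901	Yes	Yes
4.71	328.0402	4.45E-08	2742	No	No
0.606	287.2457	4.93E-08	116177	Yes	Yes
4.703	550.0624	5.80E-08	3398	No	No
9.466	416.7825	5.81E-08	3475	No	No
4.704	482.1513	5.84E-08	15513	Yes	No
4.705	310.5219	6.33E-08	2155	No	No
8.958	453.8122	6.82E-08	1363	No	No
6.279	492.3678	6.96E-08	1687	No	No
4.7	587.0983	7.11E-08	2010	No	No
4.838	271.2058	7.36E-08	9064	Yes	No
3.831	358.0548	7.46E-08	2924	No	No
4.703	487.1076	7.86E-08	14291	Yes	No
5.311	503.1375	8.51E-08	3875	Yes	No
9.076	407.3296	1.03E-07	29957	Yes	Yes
4.704	535.0978	1.06E-07	4169	No	No
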