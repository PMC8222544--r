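bin	mean_upper_boundary	rsd_percent
95-100	12392001	8.2
90-95	50518	9.5
85-90	21326	10.2
80-85	12521	10.6
75-80	8428	11.2
70-75	6069	11.7
65-70	4588	12.0
60-65	3576	12.3
55-60	2837	13.0
50-55	2274	13.5
45-50	1829	14.1
40-45	1467	14.9
35-40	1158	16.1
30-35	890	17.6
25-30	657	18.9
20-25	466	19.1
15-20	322	17.2
10-15	222	13.5
5-10	152	9.7
0-5	99	6.3
0-0	0	0.0
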