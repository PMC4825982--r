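i	j	rho0_e5	rho1_e5
1	2	3045	2227
1	3	2062	1602
2	3	2549	2103
4	5	3423	2100
4	6	2382	1978
5	6	3448	2753
7	8	2584	1808
7	9	2066	1809
8	9	2464	2037
1	4	3583	2784
1	5	4690	3044
1	6	4000	3260
1	7	7372	5149
1	8	7402	5227
1	9	7322	5599
2	4	3645	2712
2	5	4762	3059
2	6	4064	3110
2	7	7653	4978
2	8	7629	5052
2	9	7650	5449
3	4	3562	2546
3	5	4924	3022
3	6	4358	3181
3	7	7737	5266
3	8	6950	5085
3	9	7447	5654
4	7	5174	3950
4	8	5327	3568
4	9	5061	3935
5	7	6113	3894
5	8	6436	4014
5	9	6217	4325
6	7	5074	3727
6	8	5706	3934
6	9	5202	3770
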