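i	j	rho0_e5	rho1_e5
1	2	1563	1346
1	3	1317	1205
2	3	1413	1346
4	5	1568	1266
4	6	1380	1126
5	6	1100	1052
7	8	2853	1653
7	9	1946	1476
8	9	2025	1569
1	4	2296	1967
1	5	2703	2110
1	6	2868	2470
1	7	7430	6103
1	8	9535	7200
1	9	8434	6775
2	4	2839	2252
2	5	3318	2436
2	6	3458	2709
2	7	8141	6587
2	8	9999	7544
2	9	9167	7136
3	4	2718	2193
3	5	3264	2486
3	6	3257	2636
3	7	7943	6539
3	8	9998	7447
3	9	8997	7022
4	7	5918	4795
4	8	7875	5971
4	9	6899	5368
5	7	5521	4631
5	8	7842	5566
5	9	6646	5222
6	7	5595	4486
6	8	7785	5645
6	9	6786	5201
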