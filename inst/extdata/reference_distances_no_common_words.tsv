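i	j	rho0_e5	rho1_e5
1	2	3792	2832
1	3	3217	2463
2	3	3734	2502
4	5	3146	2190
4	6	2930	2215
5	6	2329	1610
7	8	5918	3317
7	9	4421	2773
8	9	4770	2809
1	4	4758	3912
1	5	5742	4276
1	6	6087	4830
1	7	12574	8800
1	8	15119	9576
1	9	13490	8895
2	4	5708	4529
2	5	6385	4991
2	6	6880	5495
2	7	13323	9469
2	8	15733	10387
2	9	14113	9621
3	4	5188	4344
3	5	5887	4917
3	6	6476	5285
3	7	13391	9835
3	8	15842	10637
3	9	14244	9891
4	7	10980	7025
4	8	13905	7371
4	9	12109	6928
5	7	10346	6537
5	8	13003	7021
5	9	11673	6673
6	7	10413	6580
6	8	13288	6667
6	9	11911	6433
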