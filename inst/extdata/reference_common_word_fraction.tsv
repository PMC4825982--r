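i	j	p_e5
1	2	47554
1	3	47786
2	3	50655
4	5	41146
4	6	42454
5	6	41822
7	8	45010
7	9	46948
8	9	48173
1	4	35592
1	5	35819
1	6	36660
1	7	28978
1	8	25870
1	9	26730
2	4	32902
2	5	32499
2	6	33877
2	7	26549
2	8	24180
2	9	24643
3	4	33463
3	5	32813
3	6	34643
3	7	27572
3	8	25340
3	9	25733
4	7	33901
4	8	30387
4	9	32005
5	7	32069
5	8	27963
5	9	29994
6	7	32002
6	8	28649
6	9	30518
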