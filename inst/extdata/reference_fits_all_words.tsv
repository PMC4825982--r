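id	beta	ss_err_e7	r_squared
1	0.61	7696	0.9768
2	0.63	7574	0.9765
3	0.61	6151	0.9816
4	0.67	4317	0.9859
5	0.69	5287	0.9820
6	0.69	3993	0.9867
7	0.75	4196	0.9844
8	0.74	4337	0.9842
9	0.79	3580	0.9860
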