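id	beta	ss_err_e7	r_squared
1	0.72	5150	0.9818
2	0.69	4495	0.9847
3	0.69	5003	0.9829
4	0.77	6107	0.9771
5	0.78	5265	0.9800
6	0.79	5220	0.9800
7	0.968	11296	0.9501
8	0.979	12943	0.9403
9	0.975	10366	0.9525
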