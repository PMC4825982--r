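text	id	author	n_tw	n_pht	n_dw	n_phd
MP	1	Austen	160473	567750	7854	48747
PP	2	Austen	121763	435322	6385	39767
SS	3	Austen	119394	425822	6264	38668
TC	4	Dickens	135420	468642	9841	58760
GE	5	Dickens	186683	623079	10933	65364
OT	6	Dickens	159103	555372	10359	61072
FR	7	Tolkien	177227	617106	8644	46509
TT	8	Tolkien	143436	502303	7676	39823
RK	9	Tolkien	134462	431141	7087	36494
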