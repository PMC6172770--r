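sample	habitat	storage	replicate	biosample	dna_nm	total_reads	assembled_reads	viral_reads	votu_reads
palsa_chilled_A	palsa	chilled	A	SAMN08784142	8.09	10216080	540430	45972	26562
palsa_frozen_A	palsa	frozen	A	SAMN08784143	19.41	26000204	1279210	70200	59800
bog_frozen_A	bog	frozen	A	SAMN08784152	9.09	14499010	2611272	102944	44948
bog_frozen_B	bog	frozen	B	SAMN08784154	0.8	4446734	466018	53806	27126
bog_chilled_B	bog	chilled	B	SAMN08784153	2.95	15578086	4210756	1190166	532770
fen_chilled_A	fen	chilled	A	SAMN08784163	0.69	2108484	665226	242898	182174
fen_chilled_B	fen	chilled	B	SAMN08784165	0.37	2001976	649040	231428	168566
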