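chrom	start	end	name	window_bp
1	94450000	94580000	ABCA4	50000
1	193930000	194025000	CFH	1000000
1	170000000	170000000	D1S549	500000
2	20500000	20500000	D2S1356	500000
2	105000000	105000000	D2S1394	500000
2	205000000	205000000	D2S1384	500000
3	39260000	39280000	CX3CR1	50000
3	20000000	20000000	D3S1768	500000
3	10500000	10500000	D3S1304	500000
3	186000000	186000000	D3S3045	500000
4	90000000	90000000	D4S2368	500000
5	135000000	135000000	D5S820	500000
5	60000000	60000000	GATA12A08	500000
5	175000000	175000000	D5S1506	500000
6	29700000	33100000	HLA	50000
6	31890000	31950000	C2-CFB	50000
6	43730000	43755000	VEGF	50000
6	80620000	80660000	ELOVL4	50000
6	160100000	160115000	SOD2	50000
7	94920000	94955000	PON1	50000
9	2620000	2660000	VLDLR	50000
9	120465000	120480000	TLR4	50000
9	90000000	90000000	D9S930	500000
9	130000000	130000000	D9S934	500000
10	124210000	124230000	LOC387715-HTRA1	50000
12	12270000	12420000	LRP6	50000
19	45410000	45415000	APOE	50000
19	11000000	11000000	D19S245	500000
20	23610000	23630000	CST3	50000
20	44635000	44645000	MMP9	50000
22	40000000	40000000	D22S683	500000
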