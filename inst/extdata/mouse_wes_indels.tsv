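sample	gene	ref	alt	abundance	region	reframed_reported
1	MED15	TGTG	TGTGGTG	1	intron	No
1	ZMAT4	GA	GATA	1	intron	No
2	LOC105376360	AG	AGTGGAGGGGTATCTCG	9	intron	No
2	MED15	TGTG	TGTGGTG	3	intron	No
2	Non-annotated	ACCC	ACCCC	7	N/A	N/A
2	RAB22A	CGGGGGG	CGGGGGGG	6	intron	No
2	Non-annotated	C	CCG	1	N/A	N/A
2	JPH1	TCCCC	TCCCCCC	2	intron	No
2	Non-annotated	CAT	C	5	N/A	N/A
2	CPQ	C	CGCCG	1	intron	No
2	Non-annotated	AACAACAACAA	AACAACAA	2	N/A	N/A
3	LOC105376360	AG	AGTGGAGGGGTATCTCG	7	intron	No
3	MED15	TGTG	TGTGGTG	4	intron	No
3	Non-annotated	CCC	CCCCCGCC	1	N/A	N/A
3	Non-annotated	ACCC	ACCCC	5	N/A	N/A
3	LOC286177	TGGGGG	TGGGGGG	3	exon	Yes
3	JPH1	TCCCC	TCCCCCC	5	intron	No
3	Non-annotated	CAT	C	6	N/A	N/A
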