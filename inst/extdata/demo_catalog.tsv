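gene	chrom	pos	ref	alt
GENE2	chrDemo	7046	A	C
GENE1	chrDemo	6496	A	C
GENE3	chrDemo	3363	A	G
GENE4	chrDemo	3075	T	G
GENE2	chrDemo	6708	A	T
GENE4	chrDemo	7676	C	T
GENE5	chrDemo	7034	A	C
GENE3	chrDemo	3374	A	G
GENE5	chrDemo	1335	G	A
GENE3	chrDemo	132	G	T
GENE3	chrDemo	3926	G	T
GENE5	chrDemo	3335	C	T
GENE1	chrDemo	7844	G	T
GENE4	chrDemo	9267	C	T
GENE2	chrDemo	2791	A	G
GENE1	chrDemo	118	T	C
GENE4	chrDemo	5110	A	T
GENE2	chrDemo	6769	G	T
GENE1	chrDemo	6959	A	C
GENE5	chrDemo	439	G	A
GENE1	chrDemo	8261	A	C
GENE3	chrDemo	9055	T	A
GENE2	chrDemo	7992	G	C
GENE1	chrDemo	2521	A	T
GENE3	chrDemo	5630	G	A
GENE1	chrDemo	3140	T	G
GENE5	chrDemo	2081	G	T
GENE3	chrDemo	8240	C	T
GENE1	chrDemo	4950	G	T
GENE2	chrDemo	9576	G	T
GENE5	chrDemo	2297	C	T
GENE2	chrDemo	3547	T	C
GENE1	chrDemo	7428	A	C
GENE3	chrDemo	7356	A	T
GENE4	chrDemo	1059	T	C
GENE5	chrDemo	2906	T	A
GENE5	chrDemo	2520	T	G
GENE4	chrDemo	2207	G	T
GENE5	chrDemo	4322	T	G
GENE4	chrDemo	9251	C	G
GENE4	chrDemo	5626	G	A
GENE5	chrDemo	9065	C	G
GENE2	chrDemo	9188	G	A
GENE1	chrDemo	6033	A	T
GENE1	chrDemo	8831	G	C
GENE1	chrDemo	85	T	G
GENE4	chrDemo	5258	G	T
GENE3	chrDemo	3076	T	C
GENE4	chrDemo	8471	C	T
GENE4	chrDemo	5541	C	A
GENE2	chrDemo	7111	A	G
GENE2	chrDemo	7496	A	G
GENE4	chrDemo	8375	C	T
GENE2	chrDemo	9629	T	G
GENE2	chrDemo	8965	G	A
GENE3	chrDemo	4350	T	C
GENE5	chrDemo	3024	G	T
GENE3	chrDemo	8712	G	C
GENE3	chrDemo	5224	A	T
GENE5	chrDemo	7928	A	T
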