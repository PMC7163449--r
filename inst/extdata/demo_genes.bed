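chr1	999	1200	GENEA	0	+
chr1	1899	2100	GENEA	0	+
chr1	29999	30200	GENEB	0	-
chr1	30899	31100	GENEB	0	-
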