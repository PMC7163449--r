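name	pam	pam_side	spacer_len	seed_len
SpCas9	NGG	3prime	20	8
SaCas9	NNGRRT	3prime	21	8
LbCpf1	TTTV	5prime	23	6
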