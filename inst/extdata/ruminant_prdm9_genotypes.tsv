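species	genotype	n
Bos taurus	AA	1
Bos taurus	BB	10
Bos taurus	CC	1
Bos taurus	AB	2
Bos taurus	BC	10
Bos taurus	AC	1
Bos indicus	AA	15
Bos indicus	BB	2
Bos indicus	CC	3
Bos indicus	AB	9
Bos indicus	BC	4
Bos indicus	AC	7
Bos taurus-Bos indicus hybrid	AA	4
Bos taurus-Bos indicus hybrid	BB	12
Bos taurus-Bos indicus hybrid	CC	1
Bos taurus-Bos indicus hybrid	DD	1
Bos taurus-Bos indicus hybrid	AB	13
Bos taurus-Bos indicus hybrid	BC	8
Bos taurus-Bos indicus hybrid	AC	1
Bos grunniens	AA	10
Bos frontalis	AA	3
Bos frontalis	BB	7
Bos frontalis	AB	10
Capra hircus	CC	1
Capra hircus	DD	3
Capra hircus	EE	2
Capra hircus	FF	8
Capra hircus	GG	1
Capra hircus	CD	2
Capra hircus	DE	4
Capra hircus	EF	3
Capra hircus	FG	6
Capra hircus	CE	1
Capra hircus	DF	7
Capra hircus	EG	1
Capra hircus	CF	3
Capra hircus	DG	2
Capra hircus	CG	1
Ovis aries	DD	41
Ovis aries	CD	4
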