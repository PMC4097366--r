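geneA	geneB	score
CUL3	COPS5	950
GPS1	COPS5	920
COPS4	COPS6	910
GSK3B	NEDD4	905
SUMO1	HDAC1	450
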