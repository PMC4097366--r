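source	yeast_id	human_symbol
demo	G0101	CUL3
demo	G0102	GPS1
demo	G0103	COPS4
demo	G0104	COPS6
demo	G0105	COPS5
demo	NBX1	COPS5
demo	G0201	GSK3B
demo	G0202	NEDD4
demo	G0203	SUMO1
demo	G0204	HDAC1
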