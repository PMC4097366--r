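geneA	geneB	score
G0101	G0102	950
G0103	NBX1	920
G0104	NBX1	910
G0201	G0202	930
G0050	G0101	400
G0060	G0061	880
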