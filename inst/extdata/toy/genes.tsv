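gene_id	symbol	length_bp	curated	gene_class
g1	Actb	2000	TRUE	ordinary
g2	Gapdh	1500	TRUE	ordinary
g3	mt-Nd1	900	TRUE	mito
g4	Rpl13a	700	TRUE	ribo
ERCC-00130	ERCC-00130	1023	TRUE	spikein
g6	Novel1	NA	TRUE	ordinary
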