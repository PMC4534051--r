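EGFR	protein-protein binding	GRB2	1
EGFR	activation	MAPK1	0
GRB2	binding	SOS1	1
SOS1	activation	HRAS	1
HRAS	activation	RAF1	1
RAF1	biochemical modification	MAP2K1	1
MAP2K1	biochemical modification	MAPK1	1
MAPK1	transcription	JUN	0
JUN	protein-protein binding	FOS	1
TP53	expression	CDKN1A	1
MAPK1	inhibition	TP53	0
EGFR	inhibition	CDKN1A	0
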