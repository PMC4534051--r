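platinum	focus genes, platinum-induced neuropathy	ABCC1	ABCC2	ABCG2	ACYP2	AGXT	BTG4	CAMK2N1	CCNH	DLEU7	ERCC1	FARS2	FOXC1	GMDS	GSTM1	GSTM3	GSTP1	ITGA1	ITGB3	KCNN3	LYRM4	PELO	POU2AF1	SCN10A	SCN4A	TAC1	TSPYL6
taxane	focus genes, taxane-induced neuropathy	ABCB1	ABCC2	ABCG1	CYP1B1	CYP2C8	CYP3A4	CYP3A5	EPHA4	EPHA5	EPHA6	FANCD2	FGD4	FZD3	GSTP1	LIMK2	SLCO1B1	SPIDR	TUBB2A	XKR4
platinum/taxane	focus genes, platinum/taxane-induced neuropathy	ABCA1	BCL2	CYP2C8	ERCC1	OPRM1	SOX10	TRPV1
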