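gene	connections	is_focus
TP53	42	FALSE
BCL2	28	TRUE
MYC	16	FALSE
PARP1	16	FALSE
P38 MAPK	15	FALSE
TNF	15	FALSE
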