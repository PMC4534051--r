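gene	connections	is_focus
IL6	70	FALSE
TNF	69	FALSE
CXCL8	56	FALSE
IL1B	55	FALSE
ERK1/2	54	FALSE
VEGFA	52	FALSE
MAPK1	51	FALSE
NFkB (complex)	46	FALSE
P38 MAPK	45	FALSE
TGFB1	43	FALSE
COL18A1	42	FALSE
CCL2	39	FALSE
IFNG	38	FALSE
PTGS2	37	FALSE
ERK	34	FALSE
TP53	34	FALSE
MAPK3	33	FALSE
Akt	32	FALSE
STAT3	30	FALSE
CD3	29	FALSE
JUN	29	FALSE
PI3K (complex)	29	FALSE
EGFR	28	FALSE
MMP1	28	FALSE
HGF	27	FALSE
Jnk	27	FALSE
CCL5	26	FALSE
CD40	26	FALSE
IL1A	26	FALSE
ITGB1	26	FALSE
MMP2	25	FALSE
Cg	24	FALSE
FN1	24	FALSE
RELA	24	FALSE
TLR4	23	FALSE
Vegf	23	FALSE
CXCL10	22	FALSE
EGF	21	FALSE
ITGB3	21	TRUE
MAPK14	21	FALSE
NFKBIA	21	FALSE
SP1	21	FALSE
STAT1	21	FALSE
AKT1	20	FALSE
HIF1A	20	FALSE
SRC	20	FALSE
TERT	20	FALSE
Pkc(s)	19	FALSE
CTNNB1	18	FALSE
Focal adhesion kinase	18	FALSE
FOS	18	FALSE
HDAC1	18	FALSE
IgG	18	FALSE
ITGAV	18	FALSE
NFKB1	18	FALSE
CD44	17	FALSE
FGF2	17	FALSE
Lh	17	FALSE
MAPK8	17	FALSE
SYK	17	FALSE
Ap1	16	FALSE
CCND1	16	FALSE
IGF1	16	FALSE
PRKCD	16	FALSE
TREM1	16	FALSE
OSM	15	FALSE
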