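gene	panel	tag
UBE2L6	A	NA
UBA7	A	NA
TRIM22	A	NA
TRIM25	A	NA
RNF125	A	NA
CBL	A	NA
CBLB	A	NA
ITCH	A	NA
STUB1	A	NA
MDM2	A	NA
USP7	A	NA
USP18	A	NA
CYLD	A	NA
TNFAIP3	A	NA
OTUB1	A	NA
FBXW7	A	NA
IFI16	B	production
MYD88	B	production
TLR3	B	production
DDX58	B	production
IFIH1	B	production
MAVS	B	production
STING1	B	production
IRF3	B	production
IRF7	B	production
TBK1	B	production
JAK2	B	signaling
JAK1	B	signaling
TYK2	B	signaling
STAT1	B	signaling
STAT2	B	signaling
IRF9	B	signaling
IFNAR1	B	signaling
IFNAR2	B	signaling
ISG15	B	signaling
MX1	B	signaling
TAP1	C	NA
TAP2	C	NA
TAPBP	C	NA
PSMB8	C	NA
PSMB9	C	NA
PSMB10	C	NA
B2M	C	NA
HLA-A	C	NA
HLA-B	C	NA
HLA-C	C	NA
HLA-DQA1	C	NA
HLA-DRA	C	NA
HLA-DRB1	C	NA
HLA-DPB1	C	NA
CALR	C	NA
PDIA3	C	NA
CANX	C	NA
ERAP1	C	NA
TGFB1	D	NA
TGFB2	D	NA
TGFB3	D	NA
TGFBR1	D	NA
TGFBR2	D	NA
SMAD2	D	NA
SMAD3	D	NA
SMAD4	D	NA
SMAD7	D	NA
SKI	D	NA
SKIL	D	NA
THBS1	D	NA
NCR1	E	NA
NCR2	E	NA
NCR3	E	NA
KLRK1	E	NA
KLRC1	E	NA
KLRD1	E	NA
FCGR3A	E	NA
KIR2DL1	E	NA
KIR2DL3	E	NA
NKG7	E	NA
KLRB1	E	NA
GNLY	E	NA
CD40	F	NA
CD40LG	F	NA
CD80	F	NA
CD86	F	NA
CD83	F	NA
CCR7	F	NA
IL12A	F	NA
IL12B	F	NA
BATF3	F	NA
ITGAX	F	NA
CD1C	F	NA
FLT3	F	NA
IL6	G	NA
IL10	G	NA
TNF	G	NA
CXCL8	G	NA
CCL2	G	NA
CCL5	G	NA
VEGFA	G	NA
HIF1A	G	NA
ARG1	G	NA
NOS2	G	NA
IDO1	G	NA
PTGS2	G	NA
CSF1R	G	NA
CD163	G	NA
CD8A	H	NA
CD8B	H	NA
CD3D	H	NA
CD3E	H	NA
GZMA	H	NA
GZMB	H	NA
PRF1	H	NA
IFNG	H	NA
IFNGR1	H	NA
PDCD1	H	NA
CD274	H	NA
CTLA4	H	NA
LAG3	H	NA
HAVCR2	H	NA
CXCL9	H	NA
CXCL10	H	NA
CXCL11	H	NA
CXCR3	H	NA
TBX21	H	NA
EOMES	H	NA
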