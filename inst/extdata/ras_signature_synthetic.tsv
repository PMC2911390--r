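gene_symbol	arm
FOS	up
FOSL1	up
FOSB	up
JUN	up
JUNB	up
EGR1	up
IER2	up
IER3	up
IER5	up
ATF3	up
DUSP1	up
DUSP4	up
DUSP5	up
DUSP6	up
SPRY1	up
SPRY2	up
SPRY4	up
SPRED1	up
SPRED2	up
ETV1	up
ETV4	up
ETV5	up
ELK3	up
PHLDA1	up
PHLDA2	up
EPHA2	up
EPHA4	up
EPHB2	up
AREG	up
EREG	up
TGFA	up
HBEGF	up
VEGFA	up
CXCL8	up
IL1B	up
IL11	up
LIF	up
SERPINE1	up
SERPINB2	up
PLAU	up
PLAUR	up
TIMP1	up
MMP1	up
MMP9	up
MMP14	up
ITGA2	up
LAMC2	up
LAMB3	up
CD55	up
GJA1	up
CCND1	up
MYC	up
TRIB1	up
TRIB2	up
GDF15	up
KITLG	up
SLC16A1	up
SLC2A1	up
SLC20A1	up
SLCO4A1	up
ANXA1	up
S100A6	up
CAV1	up
CAV2	up
VIM	up
FN1	up
TNC	up
CCN2	up
CCN1	up
F3	up
PTGS2	up
PTGES	up
LOX	up
UPP1	up
ENO2	up
GLRX	up
TXNRD1	up
NQO1	up
SQSTM1	up
MAP2K3	up
RASGRP1	up
RREB1	up
GPRC5A	up
KRT17	up
KRT6A	up
KRT16	up
SFN	up
WNT5A	up
JAG1	up
NT5E	up
CD44	up
ANGPTL4	up
ADAM17	up
ADAM19	up
PPP1R15A	up
GADD45A	up
KLF6	up
MAFF	up
BHLHE40	up
NFKBIA	up
SOCS3	up
TNFAIP3	up
RND3	up
ARL4C	up
UPK1B	up
ERBB3	down
CDH1	down
MUC1	down
SPINT1	down
SPINT2	down
ST14	down
ESRP1	down
ESRP2	down
GRHL2	down
CLDN4	down
CLDN7	down
TJP3	down
MAP7	down
MARVELD3	down
EPCAM	down
CDS1	down
DSP	down
PKP3	down
PPL	down
IRF6	down
EHF	down
ELF3	down
FOXA1	down
GATA3	down
TFAP2A	down
RAB25	down
MYO5B	down
LLGL2	down
F11R	down
EPN3	down
BSPRY	down
TMEM30B	down
AP1M2	down
CGN	down
CRB3	down
MPP7	down
PRSS8	down
SCNN1A	down
TMPRSS4	down
EPS8L1	down
C1orf116	down
GRHL1	down
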