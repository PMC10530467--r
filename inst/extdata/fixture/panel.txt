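# candidate gene panel (n = 192)
ARID4A
CRP
F2
JAK2
KLK13
NCOA1
NQO1
PEAR1
PLAT
PSG8
SAA2
SERPINA1
THBS1
UGT1A3
VWF
KIF26B
MPL
PLCG2
PTGIS
SERPIND1
TMCO1
FGB
IL1A
F5
LMOD1
KNG1
F11
SELP
PROC
ITGB3
F13A1
SAA1
HP
ORM1
NOS3
EDN1
F3
F7
F8
F9
F10
F12
F13B
FGA
FGG
PROS1
SERPINC1
SERPINE1
SERPINF2
SERPINB2
PLG
PLAU
PLAUR
THBD
PROCR
TFPI
HRG
KLKB1
ADAMTS13
CPB2
HABP2
GGCX
VKORC1
PROZ
SERPINA10
SERPING1
A2M
PZP
AMBP
MAST2
STX2
STXBP5
VAMP8
APOH
KLK8
KLK11
SLC4A1
SLC44A2
TSPAN15
F11R
GP1BA
GP1BB
GP5
GP6
GP9
ITGA2
ITGA2B
ITGB1
CD36
P2RY12
P2RY1
TBXA2R
TBXAS1
PTGS1
PTGS2
PF4
PPBP
THPO
GATA1
NFE2
RUNX1
MYB
TUBB1
MYH9
DIAPH1
RAP1B
PIK3CG
ARHGEF3
AKT1
AKT2
MAPK1
MAPK3
SRC
FYN
LYN
SYK
FCGR2A
FCER1G
PLA2G4A
PLCB2
PRKCA
PRKCB
ITPR1
ORAI1
STIM1
TRPC6
CALM1
MYL9
TLN1
VCL
ACTN1
FLNA
WAS
ANXA5
ANXA2
IL1B
IL1RN
IL6
IL6R
IL10
IL18
TNF
TNFRSF1A
TNFRSF1B
CXCL8
CCL2
ICAM1
VCAM1
SELE
SELL
PECAM1
CD40
CD40LG
C3
C5
CFH
CFB
MBL2
S100A8
S100A9
MIF
TLR2
TLR4
NLRP3
STAB2
EDNRA
EDNRB
ACE
AGT
AGTR1
REN
KLK1
BDKRB1
BDKRB2
NOS2
HMOX1
APOE
APOB
APOA1
LPL
LIPC
CETP
PCSK9
LDLR
PON1
MTHFR
MTR
CBS
NQO2
CYP2C9
ABO
FUT2
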