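# 76-gene panel for the CDH1-correlation-weighted EMT score (76GS-style).
# Weights are computed per cohort as each gene's Pearson correlation with
# CDH1, so the score needs no fixed role labels: every gene is 'signature'.
# This bundled default is a curated set of canonical epithelial and
# mesenchymal marker genes; replace it with any published 76-gene list via
# load_panel() to reproduce a specific study.
symbol	role
CDH1	signature
CLDN3	signature
CLDN4	signature
CLDN7	signature
OCLN	signature
DSP	signature
EPCAM	signature
ESRP1	signature
ESRP2	signature
GRHL2	signature
KRT5	signature
KRT8	signature
KRT14	signature
KRT18	signature
KRT19	signature
MUC1	signature
TJP1	signature
TJP3	signature
RAB25	signature
ST14	signature
VIM	signature
FN1	signature
CDH2	signature
ZEB1	signature
ZEB2	signature
SNAI1	signature
SNAI2	signature
TWIST1	signature
TWIST2	signature
FOXC2	signature
GSC	signature
PRRX1	signature
MMP2	signature
MMP3	signature
MMP9	signature
MMP14	signature
SPARC	signature
POSTN	signature
COL1A1	signature
COL1A2	signature
COL3A1	signature
COL5A1	signature
COL5A2	signature
COL6A2	signature
THBS1	signature
THBS2	signature
SERPINE1	signature
TNC	signature
LOX	signature
PDGFRA	signature
PDGFRB	signature
ACTA2	signature
TAGLN	signature
CALD1	signature
MSN	signature
EMP3	signature
BGN	signature
DCN	signature
FBN1	signature
FSTL1	signature
AHNAK	signature
HTRA1	signature
IGFBP4	signature
GEM	signature
WNT5A	signature
WNT5B	signature
TGFB1	signature
TGFB2	signature
TGFBI	signature
INHBA	signature
VCAN	signature
LUM	signature
SPP1	signature
S100A4	signature
FAP	signature
SULF1	signature
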