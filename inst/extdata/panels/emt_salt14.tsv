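# 14-gene EMT score panel: sum(9 mesenchymal) - sum(5 epithelial), log2 scale.
# Panel membership is editable; this default carries the canonical markers.
symbol	role
FN1	mesenchymal
VIM	mesenchymal
ZEB1	mesenchymal
ZEB2	mesenchymal
SNAI1	mesenchymal
SNAI2	mesenchymal
TWIST1	mesenchymal
TWIST2	mesenchymal
CDH2	mesenchymal
CDH1	epithelial
CLDN4	epithelial
CLDN7	epithelial
EPCAM	epithelial
KRT8	epithelial
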