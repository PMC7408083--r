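# 4-gene cancer-associated fibroblast (CAF) index panel
# summed log2 expression of these genes proxies CAF abundance in bulk tissue
symbol	role
FN1	caf
TGFB2	caf
TGFBR2	caf
TGFBI	caf
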