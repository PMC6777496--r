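gene	confidence	n_families
IFT81	high	2
AMMECR1	medium	1
BRD4	medium	1
FZD2	medium	2
LZTR1	medium	2
ZBED4	medium	1
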