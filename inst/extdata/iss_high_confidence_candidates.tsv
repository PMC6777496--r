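gene	n_families	n_class_V	n_class_IV	n_class_III	category_count	score_min	score_max	segregation_unavailable	tally_uncertain
CPZ	3	0	0	3	1	3	3	1	TRUE
EDEM3	2	0	0	2	3	3	3	0	TRUE
FBRS	3	0	2	1	3	3	3	1	TRUE
IFT81	2	0	0	2	2	3	3	0	FALSE
KCND1	2	0	0	2	1	3	3	0	TRUE
LAMA5	8	0	4	4	4	3	3	4	FALSE
MED24	2	1	1	0	5	4	4	0	FALSE
PLXNA3	2	0	0	2	5	3	3	0	TRUE
RASA3	2	1	1	0	4	3	4	0	FALSE
SLC7A8	2	0	0	2	3	3	3	0	TRUE
UBR4	6	0	5	1	4	2	3	4	FALSE
USP45	4	1	2	1	2	2	4	0	FALSE
ZFHX3	2	1	1	0	5	3	4	0	TRUE
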