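genotype	n_classifiable	n_elongated	n_short	n_unclassifiable	fraction_elongated
WTL	12	1	1	0	0.0833333333333333
ELG	12	12	0	0	1
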