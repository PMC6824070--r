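prediction	definitely	probably	possibly	neutral
pathogenic	33	2	2	0
probably	23	0	16	8
possibly	27	0	17	19
neutral	26	0	19	71
no score	4	0	2	2
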