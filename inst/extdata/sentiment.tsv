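# POS	term(s)	PosScore	NegScore
a	wonderful	0.75	0
a	excellent	0.875	0
a	amazing	0.75	0.125
n	relief	0.625	0
a	helpful	0.625	0
a	terrible	0	0.75
a	awful	0	0.875
a	painful	0	0.75
a	horrible	0.125	0.75
a	unbearable	0	0.625
a	good	0.625	0
a	bad	0	0.625
n	headache	0	0.375
v	hurt	0	0.5
n	heart_attack	0	0.25
r	quickly	0.125	0
n	medicine	0.125	0
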