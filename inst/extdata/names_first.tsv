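mary	female	0.996
linda	female	0.997
taylor	male	0.38
patricia	female	0.995
patricia	male	0.005
james	female	0.005
mary	male	0.004
jordan	female	0.45
robert	female	0.004
robert	male	0.996
john	male	0.994
jordan	male	0.55
taylor	female	0.62
john	female	0.006
james	male	0.995
linda	male	0.003
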