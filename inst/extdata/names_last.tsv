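yoder	black	0.005
washington	asian	0.01
smith	asian	0.01
nguyen	asian	0.96
smith	hispanic	0.04
garcia	hispanic	0.93
washington	black	0.87
martinez	black	0.01
yoder	hispanic	0.005
smith	black	0.22
garcia	asian	0.01
lee	white	0.38
nguyen	white	0.02
smith	white	0.73
washington	hispanic	0.02
lee	hispanic	0.02
nguyen	black	0.01
garcia	white	0.05
washington	white	0.1
martinez	white	0.06
martinez	asian	0.01
lee	asian	0.45
nguyen	hispanic	0.01
yoder	asian	0.005
lee	black	0.15
garcia	black	0.01
martinez	hispanic	0.92
yoder	white	0.985
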