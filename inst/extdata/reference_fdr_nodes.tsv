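hemisphere	region	r	p	ci_low	ci_high
left	fusiform	0.115	0.0030	0.04	0.19
left	superiortemporal	0.149	1.12e-04	0.08	0.22
left	temporalpole	0.121	0.0018	0.04	0.20
left	transversetemporal	0.124	0.0013	0.05	0.20
left	insula	0.117	0.0025	0.04	0.19
right	fusiform	0.140	2.86e-04	0.07	0.22
right	inferiortemporal	0.143	2.15e-04	0.07	0.22
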