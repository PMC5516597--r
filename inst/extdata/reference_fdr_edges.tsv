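hemisphere_a	region_a	hemisphere_b	region_b	r	p	ci_low	ci_high
left	fusiform	left	superiortemporal	0.130	7.95e-04	0.05	0.20
left	fusiform	left	temporalpole	0.114	0.0033	0.04	0.19
left	fusiform	left	middletemporal	0.107	0.0057	0.03	0.19
left	insula	left	pericalcarine	0.133	5.76e-04	0.06	0.21
left	insula	left	lateraloccipital	0.121	0.0018	0.04	0.20
left	insula	left	accumbens	0.120	0.0020	0.04	0.20
left	superiortemporal	left	lingual	0.189	8.87e-07	0.11	0.26
left	superiortemporal	left	pericalcarine	0.145	1.79e-04	0.07	0.21
left	superiortemporal	left	accumbens	0.139	3.21e-04	0.07	0.21
left	superiortemporal	left	insula	0.132	6.30e-04	0.06	0.21
left	superiortemporal	left	lateraloccipital	0.130	8.09e-04	0.05	0.20
left	superiortemporal	left	lateralorbitofrontal	0.123	0.0015	0.05	0.20
left	superiortemporal	left	hippocampus	0.119	0.0021	0.04	0.19
left	superiortemporal	left	caudate	0.105	0.0066	0.03	0.18
left	temporalpole	left	lingual	0.145	1.70e-04	0.06	0.22
left	temporalpole	left	accumbens	0.134	5.60e-04	0.06	0.21
left	temporalpole	left	pericalcarine	0.122	0.0016	0.05	0.19
left	temporalpole	left	caudate	0.112	0.0039	0.04	0.19
right	fusiform	right	accumbens	0.116	0.0027	0.04	0.19
right	fusiform	right	inferiortemporal	0.115	0.0030	0.04	0.19
right	inferiortemporal	right	superiortemporal	0.114	0.0032	0.04	0.18
right	inferiortemporal	right	accumbens	0.106	0.0063	0.03	0.18
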