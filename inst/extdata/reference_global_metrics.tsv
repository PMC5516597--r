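metric	r	p	ci_low	ci_high
network_cost	0.102	0.0086	0.02	0.18
global_efficiency	0.013	0.73	-0.061	0.086
clustering	-0.025	0.53	-0.093	0.054
char_path_length	0.057	0.14	-0.020	0.133
betweenness	0.013	0.73	-0.064	0.090
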