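hemisphere	region	r_degree	p_degree	r_volume	p_volume
left	superiortemporal	0.149	1.12e-04	0.008	8.44e-01
right	inferiortemporal	0.143	2.15e-04	0.011	7.75e-01
right	fusiform	0.140	2.86e-04	0.007	8.54e-01
left	transversetemporal	0.124	1.33e-03	0.027	4.88e-01
left	temporalpole	0.121	1.80e-03	0.033	4.02e-01
left	insula	0.117	2.45e-03	0.059	1.30e-01
left	fusiform	0.115	2.98e-03	0.007	8.52e-01
right	temporalpole	0.113	3.46e-03	0.016	6.85e-01
left	accumbens	0.103	7.88e-03	0.008	8.28e-01
right	parahippocampal	0.090	1.98e-02	0.067	8.25e-02
right	insula	0.088	2.30e-02	0.046	2.39e-01
right	hippocampus	0.087	2.43e-02	0.030	4.38e-01
left	isthmuscingulate	0.083	3.15e-02	0.020	6.05e-01
right	transversetemporal	0.081	3.72e-02	0.069	7.59e-02
right	putamen	0.080	3.96e-02	0.047	2.24e-01
right	lateraloccipital	0.078	4.56e-02	0.016	6.81e-01
right	superiortemporal	0.077	4.74e-02	0.001	9.83e-01
right	precentral	0.075	5.29e-02	0.016	6.87e-01
left	supramarginal	0.075	5.34e-02	0.014	7.25e-01
left	bankssts	0.073	6.07e-02	0.054	1.67e-01
left	thalamus	0.072	6.24e-02	0.032	4.11e-01
right	inferiorparietal	0.072	6.30e-02	0.019	6.34e-01
left	lateralorbitofrontal	0.071	6.82e-02	0.043	2.65e-01
right	postcentral	0.069	7.50e-02	0.042	2.85e-01
right	accumbens	0.066	8.95e-02	0.032	4.04e-01
left	caudalanteriorcingulate	0.066	9.17e-02	0.014	7.23e-01
right	amygdala	0.065	9.23e-02	0.011	7.75e-01
left	precuneus	0.065	9.47e-02	0.040	3.09e-01
right	bankssts	0.064	9.75e-02	0.040	3.05e-01
right	caudate	0.064	1.01e-01	0.029	4.55e-01
left	hippocampus	0.063	1.07e-01	0.016	6.88e-01
left	entorhinal	0.062	1.08e-01	0.102	8.65e-03
right	caudalmiddlefrontal	0.061	1.15e-01	0.078	4.33e-02
left	middletemporal	0.060	1.23e-01	0.043	2.66e-01
left	inferiorparietal	0.059	1.27e-01	0.017	6.60e-01
right	entorhinal	0.057	1.43e-01	0.070	7.18e-02
left	pallidum	0.053	1.72e-01	0.020	5.99e-01
left	posteriorcingulate	0.050	1.95e-01	0.012	7.55e-01
right	rostralmiddlefrontal	0.050	2.00e-01	0.013	7.42e-01
right	posteriorcingulate	0.049	2.10e-01	0.010	7.97e-01
left	putamen	0.044	2.56e-01	0.037	3.44e-01
left	lingual	0.043	2.66e-01	0.052	1.78e-01
left	parahippocampal	0.039	3.16e-01	0.002	9.69e-01
right	precuneus	0.039	3.17e-01	0.043	2.65e-01
right	superiorparietal	0.038	3.28e-01	0.007	8.64e-01
right	middletemporal	0.038	3.30e-01	0.051	1.87e-01
right	caudalanteriorcingulate	0.037	3.40e-01	0.053	1.75e-01
right	paracentral	0.036	3.55e-01	0.041	2.95e-01
right	isthmuscingulate	0.033	3.98e-01	0.044	2.63e-01
left	precentral	0.033	4.00e-01	0.079	4.14e-02
right	parsorbitalis	0.032	4.15e-01	0.029	4.50e-01
left	postcentral	0.030	4.40e-01	0.025	5.17e-01
left	parstriangularis	0.030	4.44e-01	0.045	2.49e-01
left	inferiortemporal	0.028	4.68e-01	0.036	3.56e-01
right	lateralorbitofrontal	0.027	4.80e-01	0.036	3.58e-01
left	paracentral	0.026	5.03e-01	0.028	4.64e-01
left	parsorbitalis	0.025	5.25e-01	0.026	5.00e-01
right	medialorbitofrontal	0.024	5.44e-01	0.007	8.63e-01
left	lateraloccipital	0.023	5.47e-01	0.018	6.41e-01
left	medialorbitofrontal	0.022	5.77e-01	0.013	7.29e-01
right	thalamus	0.020	6.07e-01	0.049	2.11e-01
left	amygdala	0.020	6.09e-01	0.062	1.09e-01
left	caudate	0.019	6.26e-01	0.024	5.41e-01
left	pericalcarine	0.017	6.59e-01	0.066	8.93e-02
right	supramarginal	0.017	6.62e-01	0.041	2.96e-01
right	cuneus	0.016	6.82e-01	0.036	3.57e-01
left	rostralanteriorcingulate	0.015	7.05e-01	0.021	5.93e-01
left	parsopercularis	0.014	7.18e-01	0.008	8.39e-01
right	lingual	0.013	7.39e-01	0.069	7.36e-02
left	caudalmiddlefrontal	0.012	7.59e-01	0.020	6.01e-01
left	rostralmiddlefrontal	0.011	7.86e-01	0.015	6.99e-01
right	parstriangularis	0.010	7.99e-01	0.006	8.76e-01
right	pallidum	0.009	8.07e-01	0.017	6.57e-01
left	superiorfrontal	0.009	8.14e-01	0.059	1.27e-01
right	parsopercularis	0.008	8.30e-01	0.032	4.06e-01
left	superiorparietal	0.008	8.44e-01	0.020	6.10e-01
left	frontalpole	0.007	8.55e-01	0.027	4.92e-01
right	superiorfrontal	0.007	8.65e-01	0.087	2.46e-02
right	frontalpole	0.006	8.85e-01	0.023	5.47e-01
left	cuneus	0.005	9.06e-01	0.094	1.50e-02
right	pericalcarine	0.001	9.81e-01	0.050	2.00e-01
right	rostralanteriorcingulate	0.000	9.99e-01	0.000	9.94e-01
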