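name	manufacturer	n_electrodes	n_markers	gaps_mm	marker_gap_mm	apical_low_intensity	alpha1_pct
Flex 28	MED-EL	12	0	2.1	NA	5	0.60
Flex 24	MED-EL	12	0	1.9	NA	5	0.96
Flex 20	MED-EL	12	0	1.5	NA	5	0.74
Flex 16	MED-EL	12	0	1.0	NA	5	2.66
MidScala	AB	16	1	0.975	3.0	0	0.49
SlimJ	AB	16	1	1.3	3.0	0	0.22
Neuro ZTI EVO	Oticon	20	0	1.2	NA	0	0.20
Hybrid-L	Cochlear	22	1	0.6-0.8	NA	0	2.37
Nucleus CI24RE (CA)	Cochlear	22	0	0.39-0.81	NA	0	0.48
Nucleus CI624	Cochlear	22	0	0.824-0.95	NA	0	0.64
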