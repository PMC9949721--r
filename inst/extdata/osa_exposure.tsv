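SNP	A1	A2	EAF	BETA	SE	P	N
rs9937053	G	A	0.43	0.104	0.012	4.30e-16	217955
rs10507084	C	T	0.18	0.104	0.016	2.80e-11	217955
rs4837016	G	A	0.47	-0.073	0.011	1.50e-08	217955
rs10928560	C	T	0.18	-0.083	0.014	2.80e-08	217955
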