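marker	allele1	allele2	Ind0	Ind0	Ind0	Ind1	Ind1	Ind1	Ind2	Ind2	Ind2
locus_00001	0	1	0.94	0.05	0.01	0.02	0.9	0.08	0.01	0.04	0.95
locus_00002	0	1	0.3333	0.3333	0.3334	0.88	0.1	0.02	0.07	0.86	0.07
locus_00003	0	1	0.64	0.32	0.04	0.49	0.42	0.09	0.25	0.5	0.25
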