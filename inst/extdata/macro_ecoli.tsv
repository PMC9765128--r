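class	g_per_gdw	soluble
protein	0.55	FALSE
rna	0.205	FALSE
dna	0.031	FALSE
lipid	0.091	FALSE
lps	0.034	FALSE
peptidoglycan	0.025	FALSE
glycogen	0.025	FALSE
polyamines	0.004	FALSE
soluble_pool	0.035	TRUE
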