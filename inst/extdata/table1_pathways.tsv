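term	name	count	p_value
hsa04080	Neuroactive ligand-receptor interaction	49	2.82e-15
hsa05322	Systemic lupus erythematosus	33	1.72e-14
hsa05034	Alcoholism	37	7.54e-14
hsa05033	Nicotine addiction	14	2.33e-08
hsa00350	Tyrosine metabolism	11	3.84e-06
hsa05204	Chemical carcinogenesis	16	5.16e-06
hsa00830	Retinol metabolism	14	8.86e-06
hsa00980	Metabolism of xenobiotics by cytochrome P450	15	9.57e-06
hsa04970	Salivary secretion	15	5.62e-05
hsa00982	Drug metabolism - cytochrome P450	13	8.52e-05
hsa04060	Cytokine-cytokine receptor interaction	26	2.69e-04
hsa04723	Retrograde endocannabinoid signaling	14	0.0011
hsa05032	Morphine addiction	13	0.0014
hsa00140	Steroid hormone biosynthesis	10	0.0017
hsa04727	GABAergic synapse	12	0.0025
hsa05202	Transcriptional misregulation in cancer	18	0.0028
hsa04972	Pancreatic secretion	12	0.0050
hsa04974	Protein digestion and absorption	11	0.0097
hsa04975	Fat digestion and absorption	7	0.0104
hsa00591	Linoleic acid metabolism	6	0.0117
hsa03320	PPAR signaling pathway	9	0.0150
hsa04024	cAMP signaling pathway	18	0.0152
hsa04976	Bile secretion	9	0.0176
hsa04724	Glutamatergic synapse	12	0.0217
hsa04913	Ovarian steroidogenesis	7	0.0297
hsa04950	Maturity onset diabetes of the young	5	0.0347
hsa00010	Glycolysis/Gluconeogenesis	8	0.0422
hsa00910	Nitrogen metabolism	4	0.0462
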