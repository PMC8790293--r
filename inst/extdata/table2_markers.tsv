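gene	degree	p_value	literature_confirmed
ADCY8	37	1.41e-32	FALSE
ADH1A	65	1.50e-167	TRUE
ADH1C	65	3.22e-87	TRUE
ADH4	65	4.01e-152	FALSE
ADH6	65	1.43e-19	FALSE
ADH7	65	1.45e-28	FALSE
AKR1C4	25	4.83e-10	TRUE
ALDH3A1	38	2.24e-70	TRUE
CYP1A2	93	3.34e-23	TRUE
CYP2A13	58	1.23e-09	FALSE
CYP2B6	62	3.57e-25	TRUE
CYP2C18	55	6.14e-17	TRUE
CYP2C19	56	1.74e-10	TRUE
CYP3A4	116	1.66e-66	TRUE
CYP3A7	43	1.59e-21	TRUE
GNG13	44	1.61e-88	FALSE
GNGT1	44	3.49e-22	FALSE
GSTA1	49	2.20e-66	TRUE
HSD3B1	52	3.17e-17	FALSE
HSD3B2	52	4.44e-53	FALSE
RXRG	64	1.15e-66	TRUE
UGT1A7	60	9.17e-43	FALSE
UGT2B28	60	2.46e-44	FALSE
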