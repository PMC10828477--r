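dataset_id	n	n_female	n_male	age_mean	age_min	age_max	Alzheimer	Schizophrenia	Normal
GSE134379	404	200	204	83.7	54	103	225	0	179
GSE59685	111	64	47	83.9	40	105	59	0	52
GSE105109	95	41	54	81.2	58	99	67	0	28
GSE125895	66	32	34	67.3	51.8	92.3	24	0	42
GSE61431	44	16	28	61.6	25	96	0	21	23
GSE72778	32	21	11	83.2	15	114	23	0	9
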