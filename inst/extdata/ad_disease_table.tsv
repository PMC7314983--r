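# Reference table of 39 AD-related diseases: symptom similarity to
# Alzheimer's disease and number of known associated proteins (UniProt).
# The AD row carries similarity 1 (similarity of AD with itself).
disease	similarity	protein_count
Dementia	0.97	123
Huntington disease	0.36	43
Brain diseases	0.35	189
Bipolar disorder	0.40	52
Neurotoxicity syndromes	0.33	17
Glioblastoma	0.34	138
Encephalitis, herpes simplex	0.42	9
Multiple sclerosis, chronic progressive	0.39	12
Brain injuries	0.48	5
Glioma	0.32	122
Psychotic disorders	0.30	17
Cocaine-related disorders	0.32	6
Hashimoto disease	0.35	145
Substance-related disorders	0.37	9
Memory disorders	0.84	26
Dementia, vascular	0.90	17
Neurodegenerative diseases	0.44	36
Cerebral amyloid angiopathy	0.36	7
Herpes simplex	0.30	91
Schizophrenia	0.46	118
Brain ischemia	0.36	57
Cadasil	0.33	2
Depressive disorder	0.34	7
Cognition disorders	0.89	8
Epilepsy, temporal lobe	0.63	25
Alcoholism	0.44	7
Amphetamine-related disorders	0.75	5
Genetic predisposition to disease	0.32	52
Mood disorders	0.51	19
Nerve degeneration	0.58	66
Brain neoplasms	0.31	55
Hyperhomocysteinemia	0.42	5
Frontotemporal dementia	0.31	31
Periventricular nodular heterotopia	0.34	7
Frontotemporal lobar degeneration	0.52	7
Depressive disorder, major	0.56	5
Lewy body disease	0.35	22
Atrophy	0.82	342
Alzheimer's Disease	1	184
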