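# Novel AD-candidate proteins with tissue-specific expression in blood.
accession	protein_name	gene	tissue
P31645	Sodium-dependent serotonin transporter	SLC6A4	Blood
P02751	Fibronectin	FN1	Blood
Q96P31	Fc receptor-like protein 3	FCRL3	Blood
Q99719	Septin-5	SEPT5	Blood
P17861	X-box-binding protein 1	XBP1	Blood
P00734	Prothrombin	F2	Blood
P01008	Antithrombin-III	SERPINC1	Blood
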