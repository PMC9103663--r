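gene	connections	n_H	size_H	n_L	size_L
GRB2	753	54	125	36	135
CTNNB1	444	81	125	62	135
SKP1	234	63	125	25	135
CSNK2A1	284	70	125	24	135
PRKDC	110	66	125	19	135
HDAC1	257	39	125	22	135
YWHAZ	522	109	125	67	135
YWHAB	310	83	125	33	135
PSMD2	132	53	125	0	135
EGFR	464	56	125	43	135
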