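drug	gene	score
RISPERIDONE	DRD2	25.88
RISPERIDONE	PRL	25.59
RISPERIDONE	HTR2A	21.38
RISPERIDONE	CYP2D6	20.21
RISPERIDONE	HTR2C	14.32
RISPERIDONE	ABCB1	13.63
RISPERIDONE	BDNF	11.93
RISPERIDONE	DRD3	11.79
RISPERIDONE	HTR1A	11.35
RISPERIDONE	CYP3A5	11.03
IBUPROFEN	PTGS2	32.79
IBUPROFEN	PTGS1	22.74
IBUPROFEN	ALB	16.90
IBUPROFEN	CYP2C9	16.71
IBUPROFEN	IL1B	15.59
IBUPROFEN	OXA1L	14.28
IBUPROFEN	IL6	13.12
IBUPROFEN	IL10	12.83
IBUPROFEN	CYP2C8	12.64
IBUPROFEN	IL1RN	11.82
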