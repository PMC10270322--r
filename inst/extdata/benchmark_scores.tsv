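set	model	etype	P	R	F1
validation	BiLSTM-CRF	overall	88.54	91.25	89.87
validation	BERT-BiLSTM-CRF	overall	89.05	92.30	90.64
validation	ALBERT-BiLSTM-CRF	overall	91.47	92.83	92.14
test	BiLSTM-CRF	overall	88.20	91.23	89.69
test	BERT-BiLSTM-CRF	overall	88.02	91.70	89.82
test	ALBERT-BiLSTM-CRF	overall	89.88	92.55	91.19
entity	BiLSTM-CRF	DRN	87.91	78.90	83.16
entity	BiLSTM-CRF	COM	89.29	93.45	91.32
entity	BiLSTM-CRF	ADR	85.50	89.86	87.63
entity	BERT-BiLSTM-CRF	DRN	83.42	80.39	81.88
entity	BERT-BiLSTM-CRF	COM	88.96	93.38	91.12
entity	BERT-BiLSTM-CRF	ADR	87.67	92.15	89.86
entity	ALBERT-BiLSTM-CRF	DRN	87.78	80.56	84.01
entity	ALBERT-BiLSTM-CRF	COM	90.28	94.42	92.30
entity	ALBERT-BiLSTM-CRF	ADR	90.09	92.73	91.39
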