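method	rank	node
Degree	1	HSPA4
Degree	2	ALYREF
Degree	3	ALDH6A1
Degree	4	HNRNPM
Degree	5	RAE1
Degree	6	CARM1
Degree	7	MRPS30
Degree	8	DBT
Degree	9	HNRNPL
Degree	10	PRPF19
Degree	11	MRPL10
Degree	12	RPL23L
Degree	13	VDAC1
Degree	14	ACAA2
Degree	15	PML
Degree	16	EIF3K
Degree	17	RPS23
Degree	18	RPS18
Degree	19	STUB1
Degree	20	GNA11
Degree	21	MLYCD
MCC	1	ALYREF
MCC	2	HSPA4
MCC	3	ALDH6A1
MCC	4	HNRNPL
MCC	5	HNRNPM
MCC	6	RAE1
MCC	7	CARM1
MCC	8	MRPS30
MCC	9	DBT
MCC	10	PRPF19
MCC	11	MRPL10
MCC	12	RPL23L
MCC	13	VDAC1
MCC	14	ACAA2
MCC	15	PML
MCC	16	EIF3K
MCC	17	RPS23
MCC	18	RPS18
MCC	19	STUB1
MCC	20	GNA11
MCC	21	MLYCD
MNC	1	ALYREF
MNC	2	HNRNPL
MNC	3	PRPF19
MNC	4	HNRNPM
MNC	5	MRPL10
MNC	6	RPL23L
MNC	7	MRPS30
MNC	8	EIF3K
MNC	9	RPS23
MNC	10	RPS18
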