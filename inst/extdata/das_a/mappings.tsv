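reaction_id	sub_met	sub_instance	element	sub_index	prod_met	prod_instance	prod_index
R1	BH4	1	C	1	BH2	1	1
R1	BH4	1	C	2	BH2	1	2
R1	BH4	1	C	3	BH2	1	3
R1	BH4	1	C	4	BH2	1	4
R1	BH4	1	C	5	BH2	1	5
R1	BH4	1	C	6	BH2	1	6
R1	BH4	1	C	7	BH2	1	7
R1	BH4	1	C	8	BH2	1	8
R1	BH4	1	C	9	BH2	1	9
R1	Phe	1	C	1	Tyr	1	1
R1	Phe	1	C	2	Tyr	1	2
R1	Phe	1	C	3	Tyr	1	3
R1	Phe	1	C	4	Tyr	1	4
R1	Phe	1	C	5	Tyr	1	5
R1	Phe	1	C	6	Tyr	1	6
R1	Phe	1	C	7	Tyr	1	7
R1	Phe	1	C	8	Tyr	1	8
R1	Phe	1	C	9	Tyr	1	9
R1	BH4	1	H	1	BH2	1	1
R1	BH4	1	H	2	BH2	1	2
R1	BH4	1	H	3	BH2	1	3
R1	BH4	1	H	4	BH2	1	4
R1	BH4	1	H	5	BH2	1	5
R1	BH4	1	H	6	BH2	1	6
R1	BH4	1	H	7	BH2	1	7
R1	BH4	1	H	8	BH2	1	8
R1	BH4	1	H	9	BH2	1	9
R1	BH4	1	H	10	BH2	1	10
R1	BH4	1	H	11	BH2	1	11
R1	BH4	1	H	12	BH2	1	12
R1	BH4	1	H	13	BH2	1	13
R1	BH4	1	H	14	H2O	1	1
R1	BH4	1	H	15	H2O	1	2
R1	Phe	1	H	1	Tyr	1	1
R1	Phe	1	H	2	Tyr	1	2
R1	Phe	1	H	3	Tyr	1	3
R1	Phe	1	H	4	Tyr	1	4
R1	Phe	1	H	5	Tyr	1	5
R1	Phe	1	H	6	Tyr	1	6
R1	Phe	1	H	7	Tyr	1	7
R1	Phe	1	H	8	Tyr	1	8
R1	Phe	1	H	9	Tyr	1	9
R1	Phe	1	H	10	Tyr	1	10
R1	Phe	1	H	11	Tyr	1	11
R1	BH4	1	N	1	BH2	1	1
R1	BH4	1	N	2	BH2	1	2
R1	BH4	1	N	3	BH2	1	3
R1	BH4	1	N	4	BH2	1	4
R1	BH4	1	N	5	BH2	1	5
R1	Phe	1	N	1	Tyr	1	1
R1	BH4	1	O	1	BH2	1	1
R1	BH4	1	O	2	BH2	1	2
R1	BH4	1	O	3	BH2	1	3
R1	O2	1	O	1	H2O	1	1
R1	O2	1	O	2	Tyr	1	3
R1	Phe	1	O	1	Tyr	1	1
R1	Phe	1	O	2	Tyr	1	2
R2	BH4	1	C	1	BH2	1	1
R2	BH4	1	C	2	BH2	1	2
R2	BH4	1	C	3	BH2	1	3
R2	BH4	1	C	4	BH2	1	4
R2	BH4	1	C	5	BH2	1	5
R2	BH4	1	C	6	BH2	1	6
R2	BH4	1	C	7	BH2	1	7
R2	BH4	1	C	8	BH2	1	8
R2	BH4	1	C	9	BH2	1	9
R2	Tyr	1	C	1	L-DOPA	1	1
R2	Tyr	1	C	2	L-DOPA	1	2
R2	Tyr	1	C	3	L-DOPA	1	3
R2	Tyr	1	C	4	L-DOPA	1	4
R2	Tyr	1	C	5	L-DOPA	1	5
R2	Tyr	1	C	6	L-DOPA	1	6
R2	Tyr	1	C	7	L-DOPA	1	7
R2	Tyr	1	C	8	L-DOPA	1	8
R2	Tyr	1	C	9	L-DOPA	1	9
R2	BH4	1	H	1	BH2	1	1
R2	BH4	1	H	2	BH2	1	2
R2	BH4	1	H	3	BH2	1	3
R2	BH4	1	H	4	BH2	1	4
R2	BH4	1	H	5	BH2	1	5
R2	BH4	1	H	6	BH2	1	6
R2	BH4	1	H	7	BH2	1	7
R2	BH4	1	H	8	BH2	1	8
R2	BH4	1	H	9	BH2	1	9
R2	BH4	1	H	10	BH2	1	10
R2	BH4	1	H	11	BH2	1	11
R2	BH4	1	H	12	BH2	1	12
R2	BH4	1	H	13	BH2	1	13
R2	BH4	1	H	14	H2O	1	1
R2	BH4	1	H	15	H2O	1	2
R2	Tyr	1	H	1	L-DOPA	1	1
R2	Tyr	1	H	2	L-DOPA	1	2
R2	Tyr	1	H	3	L-DOPA	1	3
R2	Tyr	1	H	4	L-DOPA	1	4
R2	Tyr	1	H	5	L-DOPA	1	5
R2	Tyr	1	H	6	L-DOPA	1	6
R2	Tyr	1	H	7	L-DOPA	1	7
R2	Tyr	1	H	8	L-DOPA	1	8
R2	Tyr	1	H	9	L-DOPA	1	9
R2	Tyr	1	H	10	L-DOPA	1	10
R2	Tyr	1	H	11	L-DOPA	1	11
R2	BH4	1	N	1	BH2	1	1
R2	BH4	1	N	2	BH2	1	2
R2	BH4	1	N	3	BH2	1	3
R2	BH4	1	N	4	BH2	1	4
R2	BH4	1	N	5	BH2	1	5
R2	Tyr	1	N	1	L-DOPA	1	1
R2	BH4	1	O	1	BH2	1	1
R2	BH4	1	O	2	BH2	1	2
R2	BH4	1	O	3	BH2	1	3
R2	O2	1	O	1	H2O	1	1
R2	O2	1	O	2	L-DOPA	1	4
R2	Tyr	1	O	1	L-DOPA	1	1
R2	Tyr	1	O	2	L-DOPA	1	2
R2	Tyr	1	O	3	L-DOPA	1	3
R3	L-DOPA	1	C	1	DA	1	1
R3	L-DOPA	1	C	2	DA	1	2
R3	L-DOPA	1	C	3	DA	1	3
R3	L-DOPA	1	C	4	DA	1	4
R3	L-DOPA	1	C	5	DA	1	5
R3	L-DOPA	1	C	6	DA	1	6
R3	L-DOPA	1	C	7	DA	1	7
R3	L-DOPA	1	C	8	DA	1	8
R3	L-DOPA	1	C	9	CO2	1	1
R3	H+	1	H	1	DA	1	12
R3	L-DOPA	1	H	1	DA	1	1
R3	L-DOPA	1	H	2	DA	1	2
R3	L-DOPA	1	H	3	DA	1	3
R3	L-DOPA	1	H	4	DA	1	4
R3	L-DOPA	1	H	5	DA	1	5
R3	L-DOPA	1	H	6	DA	1	6
R3	L-DOPA	1	H	7	DA	1	7
R3	L-DOPA	1	H	8	DA	1	8
R3	L-DOPA	1	H	9	DA	1	9
R3	L-DOPA	1	H	10	DA	1	10
R3	L-DOPA	1	H	11	DA	1	11
R3	L-DOPA	1	N	1	DA	1	1
R3	L-DOPA	1	O	1	CO2	1	1
R3	L-DOPA	1	O	2	CO2	1	2
R3	L-DOPA	1	O	3	DA	1	1
R3	L-DOPA	1	O	4	DA	1	2
R4	BH2	1	C	1	BH4	1	1
R4	BH2	1	C	2	BH4	1	2
R4	BH2	1	C	3	BH4	1	3
R4	BH2	1	C	4	BH4	1	4
R4	BH2	1	C	5	BH4	1	5
R4	BH2	1	C	6	BH4	1	6
R4	BH2	1	C	7	BH4	1	7
R4	BH2	1	C	8	BH4	1	8
R4	BH2	1	C	9	BH4	1	9
R4	Formate	1	C	1	CO2	1	1
R4	BH2	1	H	1	BH4	1	1
R4	BH2	1	H	2	BH4	1	2
R4	BH2	1	H	3	BH4	1	3
R4	BH2	1	H	4	BH4	1	4
R4	BH2	1	H	5	BH4	1	5
R4	BH2	1	H	6	BH4	1	6
R4	BH2	1	H	7	BH4	1	7
R4	BH2	1	H	8	BH4	1	8
R4	BH2	1	H	9	BH4	1	9
R4	BH2	1	H	10	BH4	1	10
R4	BH2	1	H	11	BH4	1	11
R4	BH2	1	H	12	BH4	1	12
R4	BH2	1	H	13	BH4	1	13
R4	Formate	1	H	1	BH4	1	14
R4	H+	1	H	1	BH4	1	15
R4	BH2	1	N	1	BH4	1	1
R4	BH2	1	N	2	BH4	1	2
R4	BH2	1	N	3	BH4	1	3
R4	BH2	1	N	4	BH4	1	4
R4	BH2	1	N	5	BH4	1	5
R4	BH2	1	O	1	BH4	1	1
R4	BH2	1	O	2	BH4	1	2
R4	BH2	1	O	3	BH4	1	3
R4	Formate	1	O	1	CO2	1	1
R4	Formate	1	O	2	CO2	1	2
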