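reaction_id	sub_met	sub_instance	element	sub_index	prod_met	prod_instance	prod_index
R1	L-DOPA	1	C	1	DA	1	1
R1	L-DOPA	1	C	2	DA	1	2
R1	L-DOPA	1	C	3	DA	1	3
R1	L-DOPA	1	C	4	DA	1	4
R1	L-DOPA	1	C	5	DA	1	5
R1	L-DOPA	1	C	6	DA	1	6
R1	L-DOPA	1	C	7	DA	1	7
R1	L-DOPA	1	C	8	DA	1	8
R1	L-DOPA	1	C	9	CO2	1	1
R1	H+	1	H	1	DA	1	12
R1	L-DOPA	1	H	1	DA	1	1
R1	L-DOPA	1	H	2	DA	1	2
R1	L-DOPA	1	H	3	DA	1	3
R1	L-DOPA	1	H	4	DA	1	4
R1	L-DOPA	1	H	5	DA	1	5
R1	L-DOPA	1	H	6	DA	1	6
R1	L-DOPA	1	H	7	DA	1	7
R1	L-DOPA	1	H	8	DA	1	8
R1	L-DOPA	1	H	9	DA	1	9
R1	L-DOPA	1	H	10	DA	1	10
R1	L-DOPA	1	H	11	DA	1	11
R1	L-DOPA	1	N	1	DA	1	1
R1	L-DOPA	1	O	1	CO2	1	1
R1	L-DOPA	1	O	2	CO2	1	2
R1	L-DOPA	1	O	3	DA	1	1
R1	L-DOPA	1	O	4	DA	1	2
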