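region	position	aa	log2fc	p_value	pct_kinked	pct_extended
FR1	12	S	1.14	5.4e-5	17.6	8.0
FR1	12	L	-0.14	2.4e-3	78.7	86.9
FR1	15	P	-0.58	3.9e-6	32.2	48.1
FR1	15	A	0.38	3.9e-5	62.3	47.9
FR1	17	D	2.32	8.5e-5	7.1	1.4
FR2	44	F	1.72	1e-45	81.0	24.5
FR2	44	Y	-2.77	1e-45	9.0	61.3
FR2	51	E	0.72	1.2e-20	79.1	47.9
FR2	51	Q	-2.63	1.7e-25	5.2	32.5
FR2	54	F	1.24	2.1e-15	45.2	19.1
FR2	54	G	2.21	9.0e-18	29.1	6.3
FR2	54	L	-2.34	1.8e-26	7.3	37.0
FR2	54	W	-1.00	6.5e-6	11.9	23.9
FR2	56	A	-0.20	1.7e-3	68.0	78.1
FR3	85	S	-1.73	3.7e-7	4.4	14.5
FR3	85	A	0.21	5.9e-5	84.3	72.6
FR3	103	V	-0.29	5.4e-7	68.0	83.2
FR3	103	I	1.45	1.3e-4	11.7	4.3
FR3	107	A	1.20	1e-45	86.8	37.9
FR3	107	N	-2.46	8.3e-21	5.2	28.8
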