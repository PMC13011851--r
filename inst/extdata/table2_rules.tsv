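number	consequent	antecedent	support	confidence	expected_confidence	lift
1	ST36	CV12	69.57	90.63	89.13	1.02
2	CV12	PC6	65.22	80.00	69.57	1.15
3	ST36	PC6	65.22	93.33	89.13	1.05
4	ST36	PC6+CV12	52.17	95.83	89.13	1.08
5	CV12	LR3	43.48	80.00	69.57	1.15
6	ST36	LR3	43.48	95.00	89.13	1.07
7	CV12	ST25	41.30	100.00	69.57	1.44
8	ST36	ST25	41.30	89.47	89.13	1.00
9	PC6	ST25+ST36	36.96	82.35	65.22	1.26
10	CV12	ST25+ST36	36.96	100.00	69.57	1.44
11	ST36	LR3+CV12	34.78	93.75	89.13	1.05
12	ST36	SP4	32.61	93.33	89.13	1.05
13	CV12	ST25+PC6	30.43	100.00	69.57	1.44
14	ST36	ST25+PC6	30.43	100.00	89.13	1.12
15	CV12	LR3+PC6	26.09	91.67	69.57	1.32
16	ST36	LR3+PC6	26.09	100.00	89.13	1.12
17	ST36	SP4+CV12	21.74	100.00	89.13	1.12
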