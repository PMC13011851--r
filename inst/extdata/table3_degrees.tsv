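cluster	code	degree
1	ST36	37
1	CV12	31
1	PC6	27
1	ST25	25
1	LR3	23
1	SP4	23
1	CV17	11
1	CV6	9
1	GV20	9
1	LI4	8
1	SP3	7
1	LR14	7
1	SI14	6
1	GB21	6
1	GB34	6
1	LR2	6
1	LR13	5
1	EX-HN5	5
1	KT3	4
1	GB41	2
1	HT7	2
2	ST44	17
2	BL20	15
2	BL21	15
2	ST40	11
2	SP9	11
2	BL15	8
2	ST23	8
2	CV11	8
2	ST42	6
3	BL18	12
3	ST21	10
3	CV4	9
3	ST37	9
3	CV13	8
3	ST2	5
3	SP6	5
3	CV10	5
3	BL17	5
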