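code	degree	betweenness	closeness	eigenvector
ST36	37	213.821861	0.974359	1
CV12	31	91.61115	0.844444	0.923906
PC6	27	66.83139	0.77551	0.828638
ST25	25	45.90043	0.745098	0.811688
LR3	23	34.60357	0.716981	0.76529
SP4	23	40.62424	0.716981	0.752505
ST44	17	8.337338	0.644068	0.666615
ST40	11	0.924242	0.584615	0.509238
BL20	15	5.189719	0.622951	0.606129
BL21	15	5.189719	0.622951	0.606129
SP9	11	1.333333	0.584615	0.486224
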