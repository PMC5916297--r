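pair	T_years	Na	Nb	Ma	Mb
SL:SN	7	39.37	18.12	3.07	0.144
SL:SF1	77	13.12	50.62	0.430	0.0294
SL:SD	4	4.38	25.62	0.0911	2.25
SL:SW	122	59.37	0.63	0.0347	0.0164
SL:SI	88	59.37	30.62	0.602	1.485
SL:SB	38	36.87	26.87	0.0730	0.222
SN:SF1	118	54.37	45.62	0.00563	2.78
SN:SD	19	16.87	40.62	0.249	0.775
SN:SW	153	56.87	0.63	0.00113	0.0194
SN:SI	18	58.12	35.62	3.11	0.655
SN:SB	242	30.62	33.12	0.448	0.0788
SF1:SD	24	24.37	100.60	0.00456	0.125
SF1:SW	41	19.37	0.63	0.258	0.0294
SF1:SI	88	63.12	119.40	0.0559	2.23
SF1:SB	264	49.37	28.12	0.266	0.419
SD:SW	106	14.37	0.63	0.0587	0.0107
SD:SI	11	10.62	83.12	0.0854	0.625
SD:SB	100	40.62	10.62	0.156	0.239
SW:SI	5	211.90	0.625	0.309	0.0676
SW:SB	156	58.12	1.88	1.21	0.0400
SI:SB	375	40.62	59.37	0.8065	0.987
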