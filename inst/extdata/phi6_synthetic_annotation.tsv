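gene	segment	start	end	frame
P7	L	101	1000	0
P2	L	1101	3098	0
P4	L	3201	4199	0
P1	L	4301	6301	0
P3	M	101	2044	0
P6	M	2101	2700	0
P10	M	2801	3025	0
P13	M	3101	3400	0
P8	S	101	550	0
P12	S	601	1200	0
P9	S	1249	1848	0
P5	S	1901	2500	0
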