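layout	level	rs0_15	rs16_19	rs20_25	rs_gt25
hotspot	lt10	1	1	3	0
hotspot	lt20	23	14	0	0
hotspot	lt30	20	8	4	2
hotspot	lt40	20	9	7	4
hotspot	ge40	12	9	6	10
average	lt10	37	19	6	3
average	lt20	32	17	11	5
average	lt30	5	5	1	1
average	lt40	2	0	2	4
average	ge40	0	0	0	3
hottest_spot	lt10	0	1	2	0
hottest_spot	lt20	14	10	1	0
hottest_spot	lt30	22	11	2	1
hottest_spot	lt40	19	7	6	4
hottest_spot	ge40	21	12	9	11
grade	1	24	9	2	1
grade	2	46	29	13	7
grade	3	6	3	5	8
combined	low	36	18	5	1
combined	high	40	23	15	15
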