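layout	level	rs0_15	rs16_19	rs20_25	rs_gt25
hotspot	lt10	4	4	3	1
hotspot	lt20	12	3	0	0
hotspot	lt30	14	3	3	2
hotspot	lt40	6	2	3	5
hotspot	ge40	4	5	7	6
average	lt10	27	10	5	2
average	lt20	12	5	6	6
average	lt30	1	2	4	2
average	lt40	0	0	1	3
average	ge40	0	0	0	1
hottest_spot	lt10	3	4	2	1
hottest_spot	lt20	8	3	1	0
hottest_spot	lt30	15	2	2	2
hottest_spot	lt40	9	3	4	3
hottest_spot	ge40	5	5	7	8
grade	1	9	4	0	2
grade	2	29	13	11	7
grade	3	2	0	5	5
combined	low	23	8	3	2
combined	high	17	9	13	12
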