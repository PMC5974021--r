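sample_id	population	language_family	lat	lon
G1P1_1	G1P1	TK	14.3	99.7
G1P1_2	G1P1	TK	14.3	99.7
G1P1_3	G1P1	TK	14.3	99.7
G1P1_4	G1P1	TK	14.3	99.7
G1P1_5	G1P1	TK	14.3	99.7
G1P1_6	G1P1	TK	14.3	99.7
G2P1_1	G2P1	AA	16.3	99.9
G2P1_2	G2P1	AA	16.3	99.9
G2P1_3	G2P1	AA	16.3	99.9
G2P1_4	G2P1	AA	16.3	99.9
G2P1_5	G2P1	AA	16.3	99.9
G2P1_6	G2P1	AA	16.3	99.9
G3P1_1	G3P1	ST	18.3	100.1
G3P1_2	G3P1	ST	18.3	100.1
G3P1_3	G3P1	ST	18.3	100.1
G3P1_4	G3P1	ST	18.3	100.1
G3P1_5	G3P1	ST	18.3	100.1
G3P1_6	G3P1	ST	18.3	100.1
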