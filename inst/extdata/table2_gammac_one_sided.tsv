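M	N0	N1	N2	N3	N4	N5	N6	N7	N8	N9	N10
1	0	0
2	0	0	18.3
3	0	0	9.0	33.5
4	0	0	5.0	20.9	44.5
5	0	0	2.8	14.7	30.8	52.6
6	0	0	1.4	10.9	23.3	38.8	58.6
7	0	0	0.4	8.3	18.5	30.7	45.2	63.4
8	0	0	0	6.4	15.0	25.2	36.9	50.5	67.1
9	0	0	0	5.0	12.5	21.2	31.0	42.1	54.8	70.2
10	0	0	0	3.9	10.5	18.2	26.7	36.1	46.6	58.5	72.8
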