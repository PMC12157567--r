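M	N0	N1	N2	N3	N4	N5	N6	N7	N8	N9	N10
1	0	0
2	0	0	11.4
3	0	0	4.7	25.5
4	0	0	1.9	15.2	36.6
5	0	0	0.3	10.2	24.6	45.1
6	0	0	0	7.2	18.2	32.5	51.7
7	0	0	0	5.2	14.1	25.3	39.1	56.9
8	0	0	0	3.7	11.3	20.5	31.5	44.6	61.1
9	0	0	0	2.6	9.2	17.1	26.2	36.8	49.2	64.6
10	0	0	0	1.8	7.5	14.4	22.4	31.3	41.5	53.2	67.5
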