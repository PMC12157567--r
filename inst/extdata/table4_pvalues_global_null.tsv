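M	N0	N1	N2	N3	N4	N5
1	1	.05
2	1	.0975	.0025
3	1	.1426	.0073	.0001
4	1	.1855	.0140	.0005	6.25e-6
5	1	.2262	.0226	.0011	3.00e-5	3.13e-7
6	1	.2649	.0328	.0022	8.64e-5	1.80e-6
7	1	.3017	.0444	.0038	.0001	6.03e-6
8	1	.3366	.0572	.0058	.0003	1.54e-5
9	1	.3698	.0712	.0084	.0006	3.32e-5
10	1	.4013	.0861	.0115	.001	6.37e-5
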