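M	N0	N1	N2	N3	N4	N5
1	1	.525
2	1	.7744	.2756
3	1	.8928	.5375	.1447
4	1	.9491	.7240	.3509	.076
5	1	.9758	.8422	.5468	.2203	.0399
6	1	.9885	.9123	.7019	.3917	.1346
7	1	.9945	.9523	.8124	.5546	.2696
8	1	.9974	.9745	.8859	.6899	.4192
9	1	.9988	.9865	.9324	.7928	.5613
10	1	.9994	.993	.9608	.8661	.6828
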