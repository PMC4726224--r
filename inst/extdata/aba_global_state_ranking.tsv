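state	n_genes
0000000	453
1111111	235
0111111	86
0001111	79
0000010	76
0000011	73
0000111	62
0011111	61
0000110	41
0000100	39
0001110	30
0001000	29
1011111	26
0001100	25
0001010	22
1110111	22
0000001	21
0001011	20
1001111	19
1111110	19
1000111	15
1111011	15
0000111	14
0001111	14
1001111	14
1000000	13
0111110	12
0000000	11
1000010	11
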