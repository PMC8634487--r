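name	letter	numeral	subtype	pattern
A2	A	2	A	111111101111111101111111111
B8	B	8	B	110111101111011101110111111
C4	C	4	C	110011101111111101111111111
D1	D	1	D	111100101110111101110101111
E2	E	2	E	111000000110011101111000111
01	0	1	NA	111000000010011101111111111
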