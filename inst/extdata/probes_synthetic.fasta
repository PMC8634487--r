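>R1
GAATACCAGTCTGCCTCCCTTTTA
>F2
ACAACCCAAACGCCGAAACGTAAA
>F5
GGATACCTCCTCCTCCTAGCGTGC
>F6
ATGTGGTTGCGTCACTGCGCGAAT
>R9
CCGCCGCGATGGCATTATTGTTGC
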