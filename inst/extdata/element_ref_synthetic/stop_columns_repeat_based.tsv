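class	column
d	1281
a	1398
b	1428
c	1458
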