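field	value
scheme	cDNA_based
key_element	15
terminal_element	26
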