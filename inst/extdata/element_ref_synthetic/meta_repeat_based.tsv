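field	value
scheme	repeat_based
key_element	10
terminal_element	27
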