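# Bimolecular duplex terms, 37 C, kcal/mol (Turner 2004 set).
key	value
duplex_init	4.10
terminal_au	0.50
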