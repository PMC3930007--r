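class	count
highly_conserved	76
conserved	22
poorly_conserved	57
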