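location	count
intergenic	95
intronic	57
exonic	2
mirtron	1
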