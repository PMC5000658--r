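gene_id	log2fc	p_value
gDown	-0.8	0.01
gUp	0.9	0.001
gUpNS	1.1	0.40
gDownNS	-0.5	0.2
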