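feature_id	contrast	log2fc	p_value	significant	direction
miR-up	aged_2w_vs_0w	1.5	0.01	1	up
miR-down	aged_2w_vs_0w	-1.2	0.02	1	down
miR-flat	aged_2w_vs_0w	0	0.9	0	unchanged
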