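mirna_id	gene_id	validated	prediction_methods
miR-up	gDown	1	
miR-up	gDown	0	m1,m2
miR-up	gDown	0	m1
miR-up	gDown	0	M1, m1
miR-up	gUp	1	
miR-up	gDownNS	1	
miR-up	gAbsent	1	
miR-down	gUp	1	
miR-down	gUpNS	1	
miR-down	gDown	0	m1,m2,m3
miR-flat	gDown	1	
miR-flat	gUp	0	m1
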