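stage	min_pcd	max_pcd	index
early_fetal	56	91	1
mid_fetal	91	182	2
late_fetal	182	280	3
infancy	280	828	4
early_childhood	828	2470	5
late_childhood	2470	4660	6
adolescence	4660	7580	7
adulthood	7580	14900	8
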