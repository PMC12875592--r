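pathway_id	pathway_name	gene
GO:0006096	glycolytic process	HK1
GO:0006096	glycolytic process	HK2
GO:0006096	glycolytic process	GPI
GO:0006096	glycolytic process	PFKL
GO:0006096	glycolytic process	PFKM
GO:0006096	glycolytic process	ALDOA
GO:0006096	glycolytic process	TPI1
GO:0006096	glycolytic process	GAPDH
GO:0006096	glycolytic process	PGK1
GO:0006096	glycolytic process	ENO1
GO:0006096	glycolytic process	PKM
GO:0006096	glycolytic process	ADPGK
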