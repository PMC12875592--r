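pathway_id	pathway_name	gene
R-HSA-70171	Glycolysis	HK1
R-HSA-70171	Glycolysis	HK2
R-HSA-70171	Glycolysis	HK3
R-HSA-70171	Glycolysis	GPI
R-HSA-70171	Glycolysis	PFKL
R-HSA-70171	Glycolysis	PFKM
R-HSA-70171	Glycolysis	ALDOA
R-HSA-70171	Glycolysis	TPI1
R-HSA-70171	Glycolysis	GAPDH
R-HSA-70171	Glycolysis	PGK1
R-HSA-70171	Glycolysis	ENO1
R-HSA-70171	Glycolysis	PKM
R-HSA-70171	Glycolysis	BPGM
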