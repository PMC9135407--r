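# Curated subset of published pan-assay interference (PAINS) substructure
# families, one pattern per line: SMARTS<TAB>name. "#" lines are comments.
# A full catalog in the same format can be supplied to load_pains().
O=C1[#6]=[#6]C(=O)[#6]=[#6]1	quinone_A
O=C1C(=O)[#6]=[#6][#6]=[#6]1	ortho_quinone_A
[OX2H]c1ccccc1[OX2H]	catechol_A
[OX2H]c1ccc([OX2H])cc1	hydroquinone_A
O=C1[#6]SC(=S)N1	rhodanine_A
[#6]=C1SC(=S)NC1=O	ene_rhod_A
c[NX2]=[NX2]c	azo_A
[OX2H]c1ccccc1[CH2][NX3]	mannich_phenol_A
[OX2H]c1ccccc1[CH]=[NX2]	hzone_phenol_A
[NX3][CX3](=S)[NX3]	thiourea_A
[#6]=[#6][CX3](=O)[#6]=[#6]	ene_one_ene_A
[OX2H]c1ccccc1N=Nc	azo_phenol_A
c1ccc2c(c1)C(=O)c1ccccc1C2=O	anthraquinone_A
[NX3]N=Cc1ccccc1[OX2H]	hydrazone_phenol_A
S=C1NC(=O)C(=C)S1	ene_thiazolidinone_A
[CX3](=O)[CX3](=O)	dicarbonyl_A
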