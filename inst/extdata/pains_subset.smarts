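# mgvs curated PAINS substructure catalog, v1 (2026-09)
# Curated subset of classic pan-assay interference substructure classes
# spanning families A/B/C; format: SMARTS<TAB>name. Lines starting with '#'
# are comments. Users may substitute a fuller catalog via the filter config.
[OX2H]c1ccccc1[OX2H]	pains_catechol
[OX2H]c1ccc([OX2H])cc1	pains_hydroquinone
O=C1C=CC(=O)C=C1	pains_para_quinone
O=C1C(=O)C=CC=C1	pains_ortho_quinone
S=C1SC(=[#6])C(=O)N1	pains_ene_rhodanine
S=C1NC(=O)C(=[#6])S1	pains_ene_rhodanine_b
O=C1NC(=O)NC(=O)C1=[#6]	pains_alkylidene_barbiturate
O=C1NC(=S)NC(=O)C1=[#6]	pains_alkylidene_thiobarbiturate
[OX2H]c1ccccc1[CH2][NX3]	pains_mannich_phenol
cN=Nc	pains_azo_aryl
[#6][NX2]=[OX1]	pains_nitroso
[NX3][NX2]=[CX3]	pains_hydrazone
NC(=S)N	pains_thiourea
[OX2H]c1ccccc1C=[NX2]	pains_hydroxyphenyl_imine
c1ccccc1C(=O)C=[CH]c1ccccc1	pains_chalcone
S1C=CC(=O)N1	pains_isothiazolone
[SX2H]c1ccccc1	pains_thiophenol
O=C1C=C(O)C(=O)C=C1	pains_hydroxyquinone
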