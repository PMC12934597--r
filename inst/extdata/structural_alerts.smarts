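# mgvs structural alert catalog, v1 (2026-09)
# Reactive / unstable substructure alerts used by the drug-likeness
# desirability score; format: SMARTS<TAB>name.
[N+](=O)[O-]	alert_nitro
[CX3H1](=O)[#6]	alert_aldehyde
C(=O)[Cl,Br,I]	alert_acyl_halide
[CX4][Br,I]	alert_alkyl_heavy_halide
C1OC1	alert_epoxide
C1NC1	alert_aziridine
N=[N+]=[N-]	alert_azide
N=C=O	alert_isocyanate
N=C=S	alert_isothiocyanate
[SX2H]	alert_thiol
[OX2][OX2]	alert_peroxide
[NX3][NX3]	alert_hydrazine
[SX2][SX2]	alert_disulfide
[#15]	alert_phosphorus
C(=O)OC(=O)	alert_anhydride
[CX3]=[CX3][CX3]=[OX1]	alert_michael_acceptor
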