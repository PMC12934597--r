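id	smiles	expected_pass	expected_rules
allene	C=C=C	FALSE	cumulated_double_bond;property:mw
butatriene	C=C=CC	FALSE	cumulated_double_bond;property:mw
cycloheptane	C1CCCCCC1	FALSE	ring_size;property:mw
cyclopropylbenzene	C1CC1c1ccccc1	FALSE	ring_size;property:mw
adamantane	C1C2CC3CC1CC(C2)C3	FALSE	ring_loop;property:mw
pentacene	c1ccc2cc3cc4cc5ccccc5cc4cc3cc2c1	FALSE	fused_count;property:logp
benzene	c1ccccc1	FALSE	property:mw
gonane	C1CC2CCC3C(CCC4CCCCC34)C2C1	FALSE	property:logp
keto_steroid	O=C1CCC2C1CCC1C2CCC2CCCCC12	TRUE	
dopa_catechol	Oc1ccc(CC(N)C(=O)O)cc1O	FALSE	pains
heptyl_hydroquinone	Oc1ccc(O)cc1CCCCCCC	FALSE	pains
rhodanine	S=C1SC(=Cc2ccccc2)C(=O)N1	FALSE	pains
azobenzene	c1ccc(cc1)N=Nc1ccccc1	FALSE	pains
tetracontane	CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	FALSE	property:mw;property:logp;property:rot_bonds
sorbitol	OCC(O)C(O)C(O)C(O)CO	FALSE	property:hbd
peg_chain	COCCOCCOCCOCCOCCOC	FALSE	property:rot_bonds
dodecanediol	OCCCCCCCCCCCCO	FALSE	property:rot_bonds
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O	TRUE	
paracetamol	CC(=O)Nc1ccc(O)cc1	TRUE	
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	TRUE	
naproxen	COc1ccc2cc(ccc2c1)C(C)C(=O)O	TRUE	
benzoylpiperidine	O=C(c1ccccc1)N1CCCCC1	TRUE	
phenytoin	O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1	TRUE	
lidocaine	CCN(CC)CC(=O)Nc1c(C)cccc1C	TRUE	
warfarin_core	CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O	TRUE	
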