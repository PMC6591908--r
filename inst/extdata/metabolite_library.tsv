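id	family	smiles
glycine	amino_acid	NCC(=O)O
alanine	amino_acid	CC(N)C(=O)O
serine	amino_acid	OCC(N)C(=O)O
threonine	amino_acid	CC(O)C(N)C(=O)O
valine	amino_acid	CC(C)C(N)C(=O)O
leucine	amino_acid	CC(C)CC(N)C(=O)O
isoleucine	amino_acid	CCC(C)C(N)C(=O)O
proline	amino_acid	OC(=O)C1CCCN1
phenylalanine	amino_acid	NC(Cc1ccccc1)C(=O)O
methionine	amino_acid	CSCCC(N)C(=O)O
glucose	monosaccharide	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O
galactose	monosaccharide	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@H]1O
mannose	monosaccharide	OC[C@H]1OC(O)[C@@H](O)[C@@H](O)[C@@H]1O
fructose	monosaccharide	OCC(=O)[C@@H](O)[C@H](O)[C@H](O)CO
xylose	monosaccharide	OC[C@@H](O)[C@H](O)[C@@H](O)C=O
ribose	monosaccharide	OC[C@H](O)[C@H](O)[C@H](O)C=O
sucrose	disaccharide	OCC1OC(CO)(OC2OC(CO)C(O)C(O)C2O)C(O)C1O
maltose	disaccharide	OCC1OC(OC2C(O)C(O)C(OC2CO)O)C(O)C(O)C1O
lactose	disaccharide	OCC1OC(OC2C(O)C(O)C(O)OC2CO)C(O)C(O)C1O
trehalose	disaccharide	OCC1OC(OC2OC(CO)C(O)C(O)C2O)C(O)C(O)C1O
citrate	organic_acid	OC(=O)CC(O)(CC(=O)O)C(=O)O
succinate	organic_acid	OC(=O)CCC(=O)O
fumarate	organic_acid	OC(=O)/C=C/C(=O)O
malate	organic_acid	OC(=O)CC(O)C(=O)O
lactate	organic_acid	CC(O)C(=O)O
pyruvate	organic_acid	CC(=O)C(=O)O
alpha_ketoglutarate	organic_acid	OC(=O)CCC(=O)C(=O)O
oxaloacetate	organic_acid	OC(=O)CC(=O)C(=O)O
adenosine	purine_nucleoside	Nc1ncnc2c1ncn2C1OC(CO)C(O)C1O
guanosine	purine_nucleoside	Nc1nc2c(ncn2C2OC(CO)C(O)C2O)c(=O)[nH]1
cytidine	pyrimidine_nucleoside	Nc1ccn(C2OC(CO)C(O)C2O)c(=O)n1
uridine	pyrimidine_nucleoside	OCC1OC(N2C=CC(=O)NC2=O)C(O)C1O
inosine	purine_nucleoside	OCC1OC(n2cnc3c2N=CNC3=O)C(O)C1O
thymidine	pyrimidine_nucleoside	CC1=CN(C2CC(O)C(CO)O2)C(=O)NC1=O
laurate	fatty_acid	CCCCCCCCCCCC(=O)O
myristate	fatty_acid	CCCCCCCCCCCCCC(=O)O
palmitate	fatty_acid	CCCCCCCCCCCCCCCC(=O)O
stearate	fatty_acid	CCCCCCCCCCCCCCCCCC(=O)O
oleate	fatty_acid	CCCCCCCC/C=C\CCCCCCCC(=O)O
linoleate	fatty_acid	CCCCC/C=C\C/C=C\CCCCCCCC(=O)O
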