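# Default functional-group SMARTS library (pattern <TAB> name).
# A compact set of common medicinal-chemistry groups; replace with your
# own curated list via readFunctionalGroups(path).
[CX3](=O)[OX2H1]	carboxylic_acid
[CX3](=O)[OX2H0][#6]	ester
[CX3](=O)[NX3]	amide
[NX3;H2,H1;!$(NC=O);!$(NS(=O)=O)]	amine
[OX2H]	hydroxyl
[OD2]([#6])[#6]	ether
[#6][CX3](=O)[#6]	ketone
[CX3H1]=O	aldehyde
[CX2]#[NX1]	nitrile
[NX3+](=O)[O-]	nitro
[F,Cl,Br,I]	halogen
[SX4](=O)(=O)[NX3]	sulfonamide
[SX2]([#6])[#6]	thioether
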