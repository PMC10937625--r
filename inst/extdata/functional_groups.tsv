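name	pattern
carbonyl	C=O
carboxylic_acid	C(=O)[OH1]
ester	C(=O)O
amide	C(=O)N
nitrile	C#N
nitro	[N+](=O)[O-]
acetal	C(O)O
imine	C=N
sulfonyl	S(=O)=O
boronic	B(O)O
fluoro	F
chloro	Cl
bromo	Br
iodo	I
aromatic_n	n
aromatic_o	o
aromatic_s	s
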