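c1ccccc1 benzene
Cc1ccccc1 toluene
CCCCCC hexane
Oc1ccccc1 phenol
Nc1ccccc1 aniline
CC(=O)O acetic_acid
CCN ethylamine
c1ccncc1 pyridine
CC(=O)C acetone
CCO ethanol
OC(=O)c1ccccc1 benzoic_acid
Clc1ccccc1 chlorobenzene
NC(=N)c1ccccc1 benzamidine
CNC dimethylamine
c1cnc[nH]1 imidazole
c1ccc2ccccc2c1 naphthalene
CCC(=O)O propanoic_acid
CN(C)C trimethylamine
CS(=O)(=O)O methanesulfonic_acid
c1ccccc1N1CCNCC1 phenylpiperazine
Cc1ccc(cc1)C(=O)O p_toluic_acid
NCCc1ccccc1 phenethylamine
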