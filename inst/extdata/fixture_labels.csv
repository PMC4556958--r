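mol_id,label
benzene,inactive
toluene,active
hexane,inactive
phenol,inactive
aniline,inactive
acetic_acid,inactive
ethylamine,inactive
pyridine,inactive
acetone,inactive
ethanol,inactive
benzoic_acid,active
chlorobenzene,active
benzamidine,active
dimethylamine,inactive
imidazole,inactive
naphthalene,active
propanoic_acid,inactive
trimethylamine,inactive
methanesulfonic_acid,inactive
phenylpiperazine,active
p_toluic_acid,active
phenethylamine,active
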