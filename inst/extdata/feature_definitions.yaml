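# Pharmacophore feature perception rules, version 1.
#
# Six feature types: A (H-bond acceptor), D (H-bond donor), H (hydrophobe),
# N (negative charge), P (positive charge), R (aromatic ring). Rules are
# interpreted on the molecular graph in the pH-7.4 protonation convention:
# carboxylic/sulfonic/phosphonic acids are treated as ionized (N), aliphatic
# amines and amidine/guanidine groups as protonated (P). Atoms claimed by a
# charged group are excluded from A and D, and an aromatic ring yields R
# only (its atoms never count as hydrophobic); a protonated amine yields P
# only (never D). This prevents double counting inside k-site tuples.
# (Single-letter keys are quoted: bare N/Y are YAML booleans.)
version: 1
ph: 7.4
features:
  "R":
    enabled: true
    # every perceived aromatic ring -> one R point at the ring centroid
  "N":
    enabled: true
    groups: [carboxylate, sulfonate, phosphonate, explicit_anion]
  "P":
    enabled: true
    groups: [aliphatic_amine, amidinium, quaternary_n, explicit_cation]
    exclude_aniline: true     # N bonded to an aromatic atom is not basic enough at pH 7.4
    exclude_amide: true       # N adjacent to C=O / C=S is not protonated
  "A":
    enabled: true
    oxygen: true              # non-aromatic O, formal charge 0, not in an acid group
    nitrogen: true            # N with no attached H, charge 0, not amide, not P-claimed
  "D":
    enabled: true
    elements: ["N", "O", "S"] # heavy atom with >= 1 attached H, charge 0, unclaimed
  "H":
    enabled: true
    halogens: ["F", "Cl", "Br", "I"]  # halogens count as hydrophobic points
    # carbon qualifies when non-aromatic, uncharged, and every neighbour is
    # C, H or halogen and not part of a charged (N/P) group; one H point per
    # connected component of qualifying atoms, at the component centroid
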