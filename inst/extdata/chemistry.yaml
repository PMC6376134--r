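# Residue chemistry tables: hydrogen-bond donors/acceptors, titratable sites,
# partial charges (e) and Lennard-Jones parameters for the coarse interface
# energy model.  version bumps on any semantic change.
version: 1

# Backbone roles shared by all amino-acid residues.  OXT (C-terminal
# carboxylate oxygen) is acidic on any residue that carries it.
# note: "N" is quoted -- a bare N is YAML 1.1 for boolean false
backbone:
  donors:
    "N": [H]
  acceptors: [O, OXT]
  acidic: [OXT]

# Side-chain roles.  donors maps heavy atom -> its covalently bonded hydrogens.
residues:
  SER: {donors: {OG:  [HG]},                          acceptors: [OG]}
  THR: {donors: {OG1: [HG1]},                         acceptors: [OG1]}
  TYR: {donors: {OH:  [HH]},                          acceptors: [OH]}
  CYS: {donors: {SG:  [HG]},                          acceptors: []}
  ASN: {donors: {ND2: [HD21, HD22]},                  acceptors: [OD1]}
  GLN: {donors: {NE2: [HE21, HE22]},                  acceptors: [OE1]}
  TRP: {donors: {NE1: [HE1]},                         acceptors: []}
  ASP: {donors: {},                                   acceptors: [OD1, OD2]}
  GLU: {donors: {},                                   acceptors: [OE1, OE2]}
  LYS: {donors: {NZ:  [HZ1, HZ2, HZ3]},               acceptors: []}
  ARG: {donors: {NE: [HE], NH1: [HH11, HH12], NH2: [HH21, HH22]}, acceptors: []}
  HIS: {donors: {ND1: [HD1], NE2: [HE2]},             acceptors: [ND1, NE2]}
  HOH: {donors: {O:   [H1, H2]},                      acceptors: [O]}

# Titratable-site tables (Methods-style salt-bridge roles): oxygens of acidic
# residues, nitrogens of basic residues.  HIS is listed basic by default
# (protonation unspecified upstream); override the table to change that.
acidic:
  ASP: [OD1, OD2]
  GLU: [OE1, OE2]
basic:
  LYS: [NZ]
  ARG: [NH1, NH2, NE]
  HIS: [ND1, NE2]

# Unit charges on titratable sites, split evenly over equivalent atoms.
charges:
  ASP: {OD1: -0.5, OD2: -0.5}
  GLU: {OE1: -0.5, OE2: -0.5}
  LYS: {NZ: 1.0}
  ARG: {NH1: 0.5, NH2: 0.5}
  HIS: {ND1: 0.5, NE2: 0.5}

# Generic Lennard-Jones parameters: declared, not fitted.
lj:
  default_epsilon: 0.1   # kcal/mol, heavy atoms
  default_sigma: 3.5     # Angstrom
  hydrogen_epsilon: 0.0
  hydrogen_sigma: 1.0
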