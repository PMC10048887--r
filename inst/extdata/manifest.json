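{
  "alpha_bare": {
    "file": "alpha_bare.csv",
    "table": 1,
    "n_rows": 17,
    "description": "Corrected Gibbs free energies (hartree) of the enzyme-free alpha-pinene allyl radicals and hydroxylated products at every abstraction site, with the published kcal/mol values relative to the most stable structure of each set."
  },
  "beta_bare": {
    "file": "beta_bare.csv",
    "table": 2,
    "n_rows": 18,
    "description": "Corrected Gibbs free energies (hartree) of the enzyme-free beta-pinene allyl radicals and hydroxylated products, with the published relative kcal/mol values."
  },
  "rs_coordinates": {
    "file": "rs_coordinates.csv",
    "table": 3,
    "n_rows": 12,
    "description": "Relative Gibbs free-energy coordinates (kcal/mol, referenced to the most stable coordinate-1 structure) of the R and S alpha-pinene enantiomers along the epsilon cis/trans doublet abstraction paths; the two enantiomers agree to 0.01 kcal/mol."
  },
  "beta_descriptors": {
    "file": "beta_descriptors.csv",
    "table": 4,
    "n_rows": 8,
    "description": "Kinetic and thermodynamic descriptors (kcal/mol) of hydrogen abstraction from beta-pinene by the CYP model: electronic, enthalpic and Gibbs reaction energies and barriers, their dispersion/BSSE/quasi-harmonic corrected variants, and the hydroxylation free energy (product IV minus reactant I)."
  },
  "beta_coordI": {
    "file": "beta_coordI.csv",
    "table": 5,
    "n_rows": 8,
    "description": "Gibbs free energies (hartree) and published Boltzmann populations of the CYP + beta-pinene reactant-complex conformers at reaction coordinate I."
  },
  "beta_coordIII": {
    "file": "beta_coordIII.csv",
    "table": 6,
    "n_rows": 8,
    "description": "Gibbs free energies (hartree) and published Boltzmann populations of the beta-pinene radical conformers at reaction coordinate III."
  },
  "alpha_descriptors": {
    "file": "alpha_descriptors.csv",
    "table": 7,
    "n_rows": 10,
    "description": "Kinetic and thermodynamic descriptors (kcal/mol) of hydrogen abstraction from alpha-pinene by the CYP model, same schema as the beta-pinene descriptor set."
  },
  "alpha_coordI": {
    "file": "alpha_coordI.csv",
    "table": 8,
    "n_rows": 10,
    "notes": "The alpha-quartet row is shipped verbatim but tagged suspect=TRUE: its printed G (-1976.024096 hartree) implies a negligible Boltzmann weight, inconsistent with its printed 20.9% population; all other rows are mutually consistent as population ratios.",
    "description": "Gibbs free energies (hartree) and published Boltzmann populations of the CYP + alpha-pinene reactant-complex conformers at reaction coordinate I."
  },
  "alpha_coordIII": {
    "file": "alpha_coordIII.csv",
    "table": 9,
    "n_rows": 10,
    "description": "Gibbs free energies (hartree) and published Boltzmann populations of the alpha-pinene radical conformers at reaction coordinate III."
  }
}
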