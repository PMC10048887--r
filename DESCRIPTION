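Package: pinetics
Title: Multistate Reaction Energetics of Pinene Hydroxylation by a Cytochrome P450 Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for multistate (doublet/quartet/sextet)
    reaction energetics of cytochrome P450 hydrogen abstraction and oxygen
    rebound on alpha- and beta-pinene. Assembles corrected Gibbs free energies
    from tabulated stationary-point records, computes relative potential-energy
    surfaces, Boltzmann conformer populations at reaction-coordinate stages,
    Eyring transition-state-theory rate constants, and rigid-rotor
    harmonic-oscillator thermochemistry with the Grimme quasi-harmonic
    free-rotor interpolation for low-frequency modes. Ships the published
    stationary-point tables for the pinene/CYP system as machine-readable
    reference sets together with a synthetic ensemble generator with known
    analytic populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
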