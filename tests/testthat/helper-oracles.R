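# Independent closed-form oracles, coded separately from the package with
# their own constants, used to cross-check the statistical-mechanics and
# thermochemistry implementations.

orc <- list(h = 6.62607015e-34, kB = 1.380649e-23, c_cm = 2.99792458e10,
            kB_Eh = 3.166811563e-6, R_kcal = 1.98720425864e-3,
            NA_ = 6.02214076e23, Eh_J = 4.3597447222071e-18)

# Harmonic-oscillator mode entropy, Eh/K.
oracle_ho_entropy <- function(nu, T) {
  x <- orc$h * orc$c_cm * nu / (orc$kB * T)
  (x / (exp(x) - 1) - log(1 - exp(-x))) * orc$kB_Eh
}

# Grimme free-rotor mode entropy, Eh/K.
oracle_fr_entropy <- function(nu, T, B) {
  mu <- orc$h / (8 * pi^2 * orc$c_cm * nu)
  mup <- mu * B / (mu + B)
  (0.5 + log(sqrt(8 * pi^3 * mup * orc$kB * T) / orc$h)) * orc$kB_Eh
}

# Mode-by-mode quasi-harmonic total, Eh/K.
oracle_qrrho_entropy <- function(freqs, T, nu0 = 100, alpha = 4, B = 1e-44) {
  total <- 0
  for (nu in freqs[freqs > 0]) {
    w <- 1 / (1 + (nu0 / nu)^alpha)
    total <- total + w * oracle_ho_entropy(nu, T) +
      (1 - w) * oracle_fr_entropy(nu, T, B)
  }
  total
}

# Sackur-Tetrode translational entropy (molar J/(mol K), then per molecule
# in Eh/K via Avogadro and the hartree).
oracle_trans_entropy <- function(mass_gmol, T, p_atm) {
  R <- orc$kB * orc$NA_
  m <- mass_gmol * 1e-3 / orc$NA_
  q <- (2 * pi * m * orc$kB * T / orc$h^2)^1.5 * orc$kB * T / (p_atm * 101325)
  S_molar <- R * (log(q) + 2.5)
  S_molar / orc$NA_ / orc$Eh_J
}

# Linear rigid-rotor entropy, Eh/K.
oracle_rot_entropy_linear <- function(I_kgm2, sigma, T) {
  q <- 8 * pi^2 * I_kgm2 * orc$kB * T / (sigma * orc$h^2)
  (log(q) + 1) * orc$kB_Eh
}

# Eyring rate constant, 1/s, barrier in kcal/mol.
oracle_eyring <- function(dg, T, kappa = 1) {
  kappa * orc$kB * T / orc$h * exp(-dg / (orc$R_kcal * T))
}

# Boltzmann mole fractions from gaps in kcal/mol (direct formula).
oracle_populations_kcal <- function(gaps, T) {
  w <- exp(-gaps / (orc$R_kcal * T))
  w / sum(w)
}

# Printed-precision comparison: number of decimals in the printed string.
printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
}
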