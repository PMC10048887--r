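# Statistical thermochemistry from harmonic frequencies: ideal-gas
# rigid-rotor harmonic-oscillator (RRHO) partition functions, with the Grimme
# quasi-harmonic treatment interpolating each low-frequency mode between the
# harmonic-oscillator and free-rotor entropy expressions.

#' Harmonic-oscillator entropy of a single vibrational mode
#'
#' S = R[ x/(e^x - 1) - ln(1 - e^-x) ] with x = h c nu / (k T). Returned per
#' molecule in hartree/K (divide the molar expression by Avogadro's number and
#' convert J to Eh).
#'
#' @param frequency wavenumber, cm^-1, strictly positive.
#' @param temperature K, strictly positive.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Entropy in hartree/K (vectorised over \code{frequency}).
#' @export
rrho_mode_entropy <- function(frequency, temperature,
                              constants = pin_constants()) {
  if (any(frequency <= 0)) stop("frequency must be > 0 (real mode)")
  if (temperature <= 0) stop("temperature must be > 0")
  x <- constants$planck * constants$speed_of_light * frequency /
    (constants$boltzmann_si * temperature)
  s_dimless <- x / expm1(x) - log(-expm1(-x))   # S / k_B
  s_dimless * constants$boltzmann_hartree
}

#' Free-rotor entropy of a single low-frequency mode
#'
#' Grimme's construction: the mode is assigned an effective rotor moment
#' mu = h / (8 pi^2 c nu), damped against an average molecular moment
#' \code{b_av} through mu' = mu b_av / (mu + b_av), and the one-dimensional
#' free-rotor entropy S = R[1/2 + ln( sqrt(8 pi^3 mu' k T) / h )] is used.
#'
#' @param frequency wavenumber, cm^-1, strictly positive.
#' @param temperature K.
#' @param b_av average molecular moment of inertia, kg m^2 (default 1e-44,
#'   the canonical value of the quasi-harmonic scheme).
#' @param constants a \code{\link{pin_constants}} object.
#' @return Entropy in hartree/K (vectorised over \code{frequency}).
#' @export
free_rotor_mode_entropy <- function(frequency, temperature, b_av = 1e-44,
                                    constants = pin_constants()) {
  if (any(frequency <= 0)) stop("frequency must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (b_av <= 0) stop("b_av must be > 0")
  h <- constants$planck
  mu <- h / (8 * pi^2 * constants$speed_of_light * frequency)
  mu_p <- mu * b_av / (mu + b_av)
  s_dimless <- 0.5 + log(sqrt(8 * pi^3 * mu_p * constants$boltzmann_si *
                                temperature) / h)
  s_dimless * constants$boltzmann_hartree
}

# Head-Gordon style damping weight: w -> 1 for nu >> nu0 (harmonic),
# w -> 0 for nu << nu0 (free rotor); w(nu0) = 1/2 exactly.
qh_damping <- function(frequency, nu0 = 100, alpha = 4) {
  1 / (1 + (nu0 / frequency)^alpha)
}

#' Quasi-harmonic vibrational entropy of a spectrum
#'
#' Total vibrational entropy with each mode interpolated between the
#' harmonic-oscillator and free-rotor expressions by the damping function
#' w(nu) = 1 / (1 + (nu0/nu)^alpha):
#' S_mode = w S_RRHO + (1 - w) S_FR. Imaginary modes (negative wavenumbers)
#' are discarded with a warning.
#'
#' @param frequencies wavenumbers, cm^-1; negatives mark imaginary modes.
#' @param temperature K.
#' @param nu0 damping crossover frequency, cm^-1 (default 100).
#' @param alpha damping exponent (default 4).
#' @param b_av free-rotor averaging moment, kg m^2.
#' @param method \code{"quasi-RRHO"} (default) or \code{"RRHO"} (pure
#'   harmonic, no interpolation).
#' @param constants a \code{\link{pin_constants}} object.
#' @return Total vibrational entropy, hartree/K, with attribute
#'   \code{per_mode} (data frame of mode-wise S_RRHO, S_FR, weight, S).
#' @export
quasi_rrho_vibrational_entropy <- function(frequencies, temperature,
                                           nu0 = 100, alpha = 4,
                                           b_av = 1e-44,
                                           method = c("quasi-RRHO", "RRHO"),
                                           constants = pin_constants()) {
  method <- match.arg(method)
  if (nu0 <= 0 || alpha <= 0) stop("nu0 and alpha must be > 0")
  imag <- frequencies < 0
  if (any(imag)) {
    warning(sum(imag), " imaginary mode(s) dropped from vibrational entropy")
    frequencies <- frequencies[!imag]
  }
  frequencies <- frequencies[frequencies > 0]
  if (length(frequencies) == 0)
    stop("no positive frequencies left after discarding imaginary modes")
  s_ho <- rrho_mode_entropy(frequencies, temperature, constants)
  if (method == "RRHO") {
    total <- sum(s_ho)
    per_mode <- data.frame(frequency = frequencies, s_rrho = s_ho,
                           s_fr = NA_real_, weight = 1, s = s_ho)
  } else {
    s_fr <- free_rotor_mode_entropy(frequencies, temperature, b_av, constants)
    w <- qh_damping(frequencies, nu0, alpha)
    s <- w * s_ho + (1 - w) * s_fr
    total <- sum(s)
    per_mode <- data.frame(frequency = frequencies, s_rrho = s_ho,
                           s_fr = s_fr, weight = w, s = s)
  }
  structure(total, per_mode = per_mode)
}

#' Ideal-gas thermochemistry of one species
#'
#' Assembles zero-point energy, thermal enthalpy and entropy components from
#' a harmonic frequency list plus molecular data, in the ideal-gas
#' rigid-rotor(-harmonic-oscillator) approximation at a given temperature and
#' pressure: Sackur-Tetrode translational entropy, classical rigid-rotor
#' rotational entropy with symmetry number, electronic entropy
#' k ln(degeneracy), and vibrational entropy in either the pure harmonic
#' (RRHO) or quasi-harmonic free-rotor-interpolated treatment. All energies
#' are per molecule in hartree; entropies in hartree/K.
#'
#' @param frequencies wavenumbers cm^-1 (negatives = imaginary, excluded).
#' @param molar_mass g/mol.
#' @param principal_moments the three principal moments of inertia, kg m^2
#'   (one value with \code{linear = TRUE}).
#' @param linear is the rotor linear?
#' @param rotational_symmetry_number integer >= 1.
#' @param electronic_degeneracy integer >= 1.
#' @param temperature K; \code{pressure} atm.
#' @param method \code{"quasi-RRHO"} or \code{"RRHO"} — they differ only in
#'   the vibrational entropy.
#' @param nu0,alpha,b_av quasi-harmonic parameters, see
#'   \code{\link{quasi_rrho_vibrational_entropy}}.
#' @param constants a \code{\link{pin_constants}} object.
#' @return A \code{thermo_result}: list with \code{zpe}, \code{h_corr},
#'   \code{s_trans}, \code{s_rot}, \code{s_vib}, \code{s_elec},
#'   \code{g_corr}, \code{method}, \code{temperature}, \code{pressure}.
#'   \code{g_corr = h_corr - T (s_trans + s_rot + s_vib + s_elec)}.
#' @export
thermochemistry <- function(frequencies, molar_mass, principal_moments,
                            linear = FALSE, rotational_symmetry_number = 1L,
                            electronic_degeneracy = 1L,
                            temperature = 298.15, pressure = 1,
                            method = c("quasi-RRHO", "RRHO"),
                            nu0 = 100, alpha = 4, b_av = 1e-44,
                            constants = pin_constants()) {
  method <- match.arg(method)
  if (molar_mass <= 0) stop("molar_mass must be > 0")
  if (any(principal_moments <= 0)) stop("moments of inertia must be > 0")
  if (temperature <= 0 || pressure <= 0) stop("T and P must be > 0")
  if (rotational_symmetry_number < 1) stop("symmetry number must be >= 1")
  if (electronic_degeneracy < 1) stop("electronic degeneracy must be >= 1")
  if (linear && length(principal_moments) != 1)
    stop("linear rotor takes a single moment of inertia")
  if (!linear && length(principal_moments) != 3)
    stop("nonlinear rotor takes three principal moments")

  kB <- constants$boltzmann_si; h <- constants$planck
  c_cm <- constants$speed_of_light
  kT <- kB * temperature
  to_Eh <- 1 / constants$hartree_joule       # J -> hartree
  kB_Eh <- constants$boltzmann_hartree

  pos <- frequencies[frequencies > 0]
  n_imag <- sum(frequencies < 0)
  if (length(pos) == 0 && length(frequencies) > 0 && n_imag == length(frequencies))
    stop("no positive frequencies (all imaginary)")

  # Vibrations: ZPE and thermal energy are always harmonic (the
  # quasi-harmonic scheme modifies only the entropy).
  if (length(pos) > 0) {
    x <- h * c_cm * pos / kT
    zpe <- sum(h * c_cm * pos / 2) * to_Eh
    u_vib_thermal <- sum(h * c_cm * pos / expm1(x)) * to_Eh
    s_vib <- suppressWarnings(
      as.numeric(quasi_rrho_vibrational_entropy(pos, temperature, nu0, alpha,
                                                b_av, method, constants)))
  } else {
    zpe <- 0; u_vib_thermal <- 0; s_vib <- 0
  }
  if (n_imag > 0)
    warning(n_imag, " imaginary mode(s) excluded from thermochemistry")

  # Translation: Sackur-Tetrode at (T, P).
  m <- molar_mass * 1e-3 / constants$avogadro      # kg per molecule
  p_pa <- pressure * constants$atm_pascal
  q_trans <- (2 * pi * m * kT / h^2)^1.5 * kT / p_pa
  s_trans <- kB_Eh * (log(q_trans) + 2.5)
  u_trans <- 1.5 * kB_Eh * temperature

  # Rotation: classical rigid rotor.
  sigma <- rotational_symmetry_number
  if (linear) {
    q_rot <- 8 * pi^2 * principal_moments[1] * kT / (sigma * h^2)
    s_rot <- kB_Eh * (log(q_rot) + 1)
    u_rot <- kB_Eh * temperature
  } else {
    q_rot <- sqrt(pi * prod(principal_moments)) / sigma *
      (8 * pi^2 * kT / h^2)^1.5
    s_rot <- kB_Eh * (log(q_rot) + 1.5)
    u_rot <- 1.5 * kB_Eh * temperature
  }

  s_elec <- kB_Eh * log(electronic_degeneracy)

  # H = U + PV = ZPE + U_vib + U_trans + U_rot + kT (per molecule, hartree).
  h_corr <- zpe + u_vib_thermal + u_trans + u_rot + kB_Eh * temperature
  s_total <- s_trans + s_rot + s_vib + s_elec
  g_corr <- h_corr - temperature * s_total

  structure(list(zpe = zpe, h_corr = h_corr, s_trans = s_trans,
                 s_rot = s_rot, s_vib = s_vib, s_elec = s_elec,
                 g_corr = g_corr, method = method,
                 temperature = temperature, pressure = pressure,
                 n_imaginary = n_imag),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Ideal-gas thermochemistry (%s) at %.2f K, %.3g atm\n",
              x$method, x$temperature, x$pressure))
  cat(sprintf("  ZPE      %14.8f Eh\n", x$zpe))
  cat(sprintf("  H corr   %14.8f Eh\n", x$h_corr))
  cat(sprintf("  S trans  %14.6e Eh/K\n", x$s_trans))
  cat(sprintf("  S rot    %14.6e Eh/K\n", x$s_rot))
  cat(sprintf("  S vib    %14.6e Eh/K\n", x$s_vib))
  cat(sprintf("  S elec   %14.6e Eh/K\n", x$s_elec))
  cat(sprintf("  G corr   %14.8f Eh\n", x$g_corr))
  if (x$n_imaginary > 0)
    cat(sprintf("  (%d imaginary mode(s) excluded)\n", x$n_imaginary))
  invisible(x)
}

#' Read a frequency-list file
#'
#' Plain text, one wavenumber (cm^-1) per line; negative values mark
#' imaginary modes; lines starting with '#' and blank lines are ignored.
#'
#' @param path file path.
#' @return Numeric vector of wavenumbers.
#' @export
read_frequencies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v)) stop("non-numeric entries in frequency file: ", path)
  v
}
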