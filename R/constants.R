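#' Physical constants and unit-conversion factors
#'
#' Returns the immutable set of physical constants used throughout the
#' package. Energies are handled internally in hartree (Eh); conversion to
#' kcal/mol happens only at reporting boundaries so that rounding never
#' accumulates. The hartree-to-kcal/mol factor defaults to 627.5095, the
#' value that reproduces the published relative-energy tables for the
#' pinene/CYP system to their printed precision.
#'
#' @param hartree_to_kcal conversion factor, kcal/mol per hartree.
#' @param boltzmann_hartree Boltzmann constant in Eh/K, applied directly to
#'   Gibbs energies in hartree when forming Boltzmann weights.
#' @param gas_constant_kcal molar gas constant in kcal/(mol K), used with
#'   barriers expressed in kcal/mol (Eyring equation).
#' @param default_temperature default thermodynamic temperature, K.
#' @param default_pressure default standard-state pressure, atm.
#'
#' @return An object of class \code{pinetics_constants}: a named list with the
#'   arguments above plus SI constants (\code{planck} J s, \code{boltzmann_si}
#'   J/K, \code{speed_of_light} cm/s, \code{avogadro} 1/mol,
#'   \code{hartree_joule} J/Eh, \code{atm_pascal} Pa/atm).
#' @examples
#' cst <- pin_constants()
#' cst$hartree_to_kcal
#' @export
pin_constants <- function(hartree_to_kcal = 627.5095,
                          boltzmann_hartree = 3.166811563e-6,
                          gas_constant_kcal = 1.98720425864e-3,
                          default_temperature = 298.15,
                          default_pressure = 1) {
  stopifnot(hartree_to_kcal > 0, boltzmann_hartree > 0,
            gas_constant_kcal > 0, default_temperature > 0,
            default_pressure > 0)
  structure(list(
    hartree_to_kcal = hartree_to_kcal,
    boltzmann_hartree = boltzmann_hartree,
    gas_constant_kcal = gas_constant_kcal,
    planck = 6.62607015e-34,          # J s (exact, SI 2019)
    boltzmann_si = 1.380649e-23,      # J/K (exact)
    speed_of_light = 2.99792458e10,   # cm/s (exact; cm because wavenumbers)
    avogadro = 6.02214076e23,         # 1/mol (exact)
    hartree_joule = 4.3597447222071e-18, # J per hartree (CODATA 2018)
    atm_pascal = 101325,
    default_temperature = default_temperature,
    default_pressure = default_pressure
  ), class = "pinetics_constants")
}

#' @export
print.pinetics_constants <- function(x, ...) {
  cat("Physical constants (pinetics)\n")
  for (nm in names(x)) cat(sprintf("  %-20s %.12g\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert energies between hartree and kcal/mol
#'
#' @param value numeric vector of energies.
#' @param from,to \code{"hartree"} or \code{"kcal/mol"}.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_energy(0.034532, "hartree", "kcal/mol")  # 21.67...
#' @export
convert_energy <- function(value, from = "hartree", to = "kcal/mol",
                           constants = pin_constants()) {
  units <- c("hartree", "kcal/mol")
  if (!from %in% units)
    stop("unknown energy unit '", from, "'; supported: ", paste(units, collapse = ", "))
  if (!to %in% units)
    stop("unknown energy unit '", to, "'; supported: ", paste(units, collapse = ", "))
  if (from == to) return(value)
  if (from == "hartree") value * constants$hartree_to_kcal
  else value / constants$hartree_to_kcal
}
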