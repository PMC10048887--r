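# Boltzmann conformer statistics over reaction-coordinate ensembles and
# Eyring transition-state-theory kinetics.

#' Conformer ensemble at one reaction-coordinate stage
#'
#' Bundles the stationary points (conformers and spin states) that coexist at
#' a single reaction-coordinate stage with the temperature at which their
#' equilibrium populations are evaluated.
#'
#' @param points data frame with a finite \code{g_hartree} column; typical
#'   label columns (\code{site}, \code{stereopath}, \code{multiplicity} or a
#'   precomputed \code{label}) are carried through.
#' @param stage reaction-coordinate stage of all members ("I"--"IV", or a
#'   bare-system stage).
#' @param temperature K, > 0.
#' @return An \code{ensemble} object.
#' @export
ensemble <- function(points, stage = "I", temperature = 298.15) {
  if (!is.data.frame(points)) points <- data.frame(g_hartree = as.numeric(points))
  if (nrow(points) == 0) stop("ensemble must be nonempty")
  if (!"g_hartree" %in% names(points)) stop("points need a g_hartree column")
  if (!all(is.finite(points$g_hartree))) stop("all g values must be finite")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  if ("stage" %in% names(points)) {
    st <- unique(points$stage[!is.na(points$stage)])
    if (length(st) > 1)
      stop("ensemble members span several stages: ", paste(st, collapse = ", "))
    if (length(st) == 1) stage <- st
  }
  structure(list(stage = stage, members = points, temperature = temperature),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Ensemble at reaction coordinate %s: %d member(s), T = %.2f K\n",
              x$stage, nrow(x$members), x$temperature))
  invisible(x)
}

#' Boltzmann populations of an ensemble
#'
#' Equilibrium mole fractions p_i = exp(-(g_i - g_min)/(kT)) / sum_j
#' exp(-(g_j - g_min)/(kT)), with the minimum subtracted before
#' exponentiation so that arbitrarily deep absolute energies never overflow.
#' g is in hartree and k is Boltzmann's constant in hartree/K, so no molar
#' conversion is involved. Each conformer counts as a single state (no
#' degeneracy factors).
#'
#' @param x an \code{\link{ensemble}}, a data frame with \code{g_hartree}, or
#'   a bare numeric vector of free energies in hartree.
#' @param temperature K; ignored (with the ensemble's own temperature used)
#'   when \code{x} is an \code{ensemble}.
#' @param constants a \code{\link{pin_constants}} object.
#' @return A \code{population_table}: data frame with columns \code{label},
#'   \code{g_hartree}, \code{mole_fraction}, \code{percent}, row order
#'   preserving the input, with attributes \code{temperature} and
#'   \code{stage}.
#' @examples
#' boltzmann_populations(c(a = -10, b = -10))  # 50/50
#' @export
boltzmann_populations <- function(x, temperature = 298.15,
                                  constants = pin_constants()) {
  stage <- NA_character_
  if (inherits(x, "ensemble")) {
    temperature <- x$temperature
    stage <- x$stage
    df <- x$members
  } else if (is.data.frame(x)) {
    df <- x
  } else {
    df <- data.frame(g_hartree = as.numeric(x))
    if (!is.null(names(x))) df$label <- names(x)
  }
  g <- df$g_hartree
  if (length(g) == 0) stop("empty ensemble")
  if (!all(is.finite(g))) stop("non-finite free energy in ensemble")
  if (temperature <= 0) stop("temperature must be > 0")
  w <- exp(-(g - min(g)) / (constants$boltzmann_hartree * temperature))
  p <- w / sum(w)
  labels <- if (!is.null(df$label)) df$label
            else if (all(c("site", "stereopath", "multiplicity") %in% names(df)))
              conformer_label(df$site, df$stereopath, df$multiplicity)
            else as.character(seq_along(g))
  out <- data.frame(label = labels, g_hartree = g, mole_fraction = p,
                    percent = 100 * p, stringsAsFactors = FALSE)
  structure(out, class = c("population_table", "data.frame"),
            temperature = temperature, stage = stage)
}

#' @export
print.population_table <- function(x, digits = 3, ...) {
  cat(sprintf("Boltzmann populations at T = %.2f K%s\n",
              attr(x, "temperature"),
              if (!is.na(attr(x, "stage")))
                sprintf(" (reaction coordinate %s)", attr(x, "stage")) else ""))
  df <- as.data.frame(x)
  df$g_hartree <- sprintf("%.6f", df$g_hartree)
  df$mole_fraction <- signif(df$mole_fraction, digits)
  df$percent <- signif(df$percent, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Eyring rate constant
#'
#' k = kappa (k_B T / h) exp(-dG' / (R T)) for a free-energy barrier dG' in
#' kcal/mol. With a zero barrier and unit transmission this is the universal
#' frequency factor k_B T / h (about 6.21e12 1/s at 298.15 K).
#'
#' @param dg_activation free-energy barrier, kcal/mol.
#' @param temperature K.
#' @param transmission transmission coefficient kappa in (0, 1]; default 1
#'   (no tunnelling correction).
#' @param constants a \code{\link{pin_constants}} object.
#' @return Rate constant, 1/s (vectorised over \code{dg_activation}).
#' @export
eyring_rate_constant <- function(dg_activation, temperature = 298.15,
                                 transmission = 1,
                                 constants = pin_constants()) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (transmission <= 0 || transmission > 1)
    stop("transmission coefficient must be in (0, 1]")
  prefactor <- constants$boltzmann_si * temperature / constants$planck
  transmission * prefactor *
    exp(-dg_activation / (constants$gas_constant_kcal * temperature))
}

#' Ratio of two Eyring rates
#'
#' k1/k2 for barriers dg1 and dg2 at the same temperature: the prefactor
#' cancels, leaving exp((dg2 - dg1)/(R T)). Values above 1 mean the path with
#' barrier \code{dg1} is faster.
#'
#' @param dg1,dg2 free-energy barriers, kcal/mol.
#' @param temperature K.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Dimensionless rate ratio.
#' @export
rate_ratio <- function(dg1, dg2, temperature = 298.15,
                       constants = pin_constants()) {
  if (temperature <= 0) stop("temperature must be > 0")
  exp((dg2 - dg1) / (constants$gas_constant_kcal * temperature))
}
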