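# Synthetic conformer ensembles and vibrational spectra with known ground
# truth. The ensemble generator prescribes free-energy gaps (kcal/mol) above
# a base structure, so the exact Boltzmann populations are known analytically
# and serve as an independent oracle for the statistical-mechanics engine:
# the analytic calculator below works on the gaps in kcal/mol through the
# molar gas constant, deliberately sharing no code (and no max-subtraction
# trick) with boltzmann_populations().

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Specify a synthetic conformer ensemble
#'
#' @param n_members number of conformers (>= 1).
#' @param gap_model \code{"uniform"} (gaps drawn uniformly on
#'   \code{[0, max_gap]}), \code{"exponential"} (mean \code{mean_gap}), or
#'   \code{"explicit"} (gaps given verbatim). The first member always sits at
#'   gap 0. Gaps are in kcal/mol.
#' @param max_gap,mean_gap,gaps parameters of the three gap models.
#' @param temperature K.
#' @param base_g absolute Gibbs energy of the most stable member, hartree.
#' @param stage reaction-coordinate stage tag.
#' @param seed integer; fully determines the generated ensemble.
#' @return An \code{ensemble_spec} object.
#' @export
ensemble_spec <- function(n_members, gap_model = c("uniform", "exponential",
                                                   "explicit"),
                          max_gap = 3, mean_gap = 1, gaps = NULL,
                          temperature = 298.15, base_g = -1976,
                          stage = "I", seed = 1L) {
  gap_model <- match.arg(gap_model)
  if (n_members < 1) stop("n_members must be >= 1")
  if (temperature <= 0) stop("temperature must be > 0")
  if (gap_model == "explicit") {
    if (is.null(gaps) || length(gaps) != n_members)
      stop("explicit gap model needs 'gaps' of length n_members")
    if (any(gaps < 0)) stop("gaps must be >= 0")
  } else if (gap_model == "uniform" && max_gap < 0) {
    stop("max_gap must be >= 0")
  } else if (gap_model == "exponential" && mean_gap <= 0) {
    stop("mean_gap must be > 0")
  }
  structure(list(n_members = as.integer(n_members), gap_model = gap_model,
                 max_gap = max_gap, mean_gap = mean_gap, gaps = gaps,
                 temperature = temperature, base_g = base_g, stage = stage,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Independent analytic Boltzmann oracle: direct closed-form weights relative
# to the first member (no minimum subtraction), on the realized free-energy
# gaps in hartree.
analytic_populations_from_gaps <- function(gaps_hartree, temperature,
                                           boltzmann_hartree = 3.166811563e-6) {
  w <- exp(-gaps_hartree / (boltzmann_hartree * temperature))
  w / sum(w)
}

#' Generate a synthetic conformer ensemble with known populations
#'
#' Draws free-energy gaps according to the spec, assembles an
#' \code{\link{ensemble}} with absolute G values \code{base_g + gap}, and
#' returns alongside it the analytically known Boltzmann populations,
#' computed by a direct closed-form evaluation on the realized gaps (weights
#' relative to the first member, no overflow-guarding minimum subtraction) —
#' an oracle sharing no code path with
#' \code{\link{boltzmann_populations}}. The realized gaps are the generated
#' absolute G values minus the first member's, so the analytic populations
#' are ground truth for the ensemble as stored, at double precision.
#'
#' @param spec an \code{\link{ensemble_spec}}.
#' @param constants a \code{\link{pin_constants}} object (conversion factor
#'   and molar gas constant).
#' @return List with \code{ensemble} and \code{analytic} (data frame
#'   \code{label, gap_kcal, mole_fraction, percent}).
#' @export
generate_ensemble <- function(spec, constants = pin_constants()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  gaps <- with_seed(spec$seed, switch(spec$gap_model,
    uniform = c(0, stats::runif(spec$n_members - 1, 0, spec$max_gap)),
    exponential = c(0, stats::rexp(spec$n_members - 1, 1 / spec$mean_gap)),
    explicit = spec$gaps))
  labels <- sprintf("conf%02d", seq_len(spec$n_members))
  members <- data.frame(
    label = labels,
    stage = spec$stage,
    g_hartree = spec$base_g + gaps / constants$hartree_to_kcal,
    stringsAsFactors = FALSE)
  p <- analytic_populations_from_gaps(members$g_hartree - members$g_hartree[1],
                                      spec$temperature,
                                      constants$boltzmann_hartree)
  list(ensemble = ensemble(members, spec$stage, spec$temperature),
       analytic = data.frame(label = labels, gap_kcal = gaps,
                             mole_fraction = p, percent = 100 * p,
                             stringsAsFactors = FALSE))
}

#' Specify a synthetic vibrational spectrum
#'
#' @param n_modes number of real modes.
#' @param range wavenumber range (min, max) in cm^-1, min > 0.
#' @param n_imaginary 0 (minimum) or 1 (transition state).
#' @param imaginary_range magnitude range for the imaginary mode, cm^-1.
#' @param seed integer.
#' @return A \code{spectrum_spec} object.
#' @export
spectrum_spec <- function(n_modes, range = c(50, 3500), n_imaginary = 0L,
                          imaginary_range = c(400, 1800), seed = 1L) {
  if (n_modes < 0) stop("n_modes must be >= 0")
  if (length(range) != 2 || range[1] <= 0 || range[2] < range[1])
    stop("range must be (min, max) with 0 < min <= max")
  if (!n_imaginary %in% c(0L, 1L))
    stop("n_imaginary must be 0 or 1 (at most one imaginary mode)")
  structure(list(n_modes = as.integer(n_modes), range = range,
                 n_imaginary = as.integer(n_imaginary),
                 imaginary_range = imaginary_range, seed = as.integer(seed)),
            class = "spectrum_spec")
}

#' Generate a synthetic harmonic spectrum
#'
#' @param spec a \code{\link{spectrum_spec}}.
#' @return Numeric vector: positive wavenumbers sorted ascending, preceded by
#'   exactly one negative entry iff \code{n_imaginary = 1}.
#' @export
generate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  with_seed(spec$seed, {
    pos <- sort(stats::runif(spec$n_modes, spec$range[1], spec$range[2]))
    if (spec$n_imaginary == 1L)
      c(-stats::runif(1, spec$imaginary_range[1], spec$imaginary_range[2]), pos)
    else pos
  })
}
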