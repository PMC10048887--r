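#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for the stationary-point table schema.
pin_molecules <- c("alpha-pinene", "beta-pinene")
pin_sites <- c("alpha", "gamma", "delta", "epsilon", "zeta", "theta",
               "iota", "kappa")
pin_stereopaths <- c("cis", "trans", "none")
pin_enantiomers <- c("R", "S", "none")
pin_multiplicities <- c(2L, 4L, 6L)   # doublet, quartet, sextet
pin_stages <- c("I", "II", "III", "IV", "bare-radical", "bare-hydroxylated")

# Sites whose two allylic hydrogens are diastereotopic, hence admit a
# cis/trans stereopath: delta of beta-pinene, epsilon of alpha-pinene.
# (The bare hydroxylated sets also distinguish cis/trans at those sites.)
pin_stereo_sites <- list("alpha-pinene" = "epsilon", "beta-pinene" = "delta")

pin_point_columns <- c("molecule", "site", "stereopath", "enantiomer",
                       "multiplicity", "stage", "e_elec_hartree", "h_hartree",
                       "g_hartree", "dispersion_hartree", "bsse_hartree",
                       "qh_hartree", "solvent_hartree")

#' Construct a species label
#'
#' Identifies one species on the multistate reaction network: which pinene,
#' which carbon site (Greek-letter nomenclature) the hydrogen is abstracted
#' from, which of the two diastereotopic allylic hydrogens (cis/trans
#' stereopath, where the site has two), the substrate enantiomer and the spin
#' multiplicity of the CYP/substrate system.
#'
#' @param molecule \code{"alpha-pinene"} or \code{"beta-pinene"}.
#' @param site one of alpha, gamma, delta, epsilon, zeta, theta, iota, kappa.
#' @param stereopath \code{"cis"}, \code{"trans"} or \code{"none"}.
#' @param enantiomer \code{"R"}, \code{"S"} or \code{"none"}.
#' @param multiplicity spin multiplicity 2S+1: 2 (doublet), 4 (quartet) or
#'   6 (sextet).
#' @return A \code{species_label} object (named list).
#' @export
species_label <- function(molecule, site, stereopath = "none",
                          enantiomer = "none", multiplicity = 2L) {
  molecule <- match.arg(molecule, pin_molecules)
  site <- match.arg(site, pin_sites)
  stereopath <- match.arg(stereopath, pin_stereopaths)
  enantiomer <- match.arg(enantiomer, pin_enantiomers)
  multiplicity <- as.integer(multiplicity)
  if (!multiplicity %in% pin_multiplicities)
    stop("multiplicity must be 2, 4 or 6 (doublet/quartet/sextet), got ",
         multiplicity)
  structure(list(molecule = molecule, site = site, stereopath = stereopath,
                 enantiomer = enantiomer, multiplicity = multiplicity),
            class = "species_label")
}

#' @export
format.species_label <- function(x, ...) {
  spin <- c(`2` = "doublet", `4` = "quartet", `6` = "sextet")[as.character(x$multiplicity)]
  parts <- c(x$site,
             if (x$stereopath != "none") x$stereopath,
             spin,
             if (x$enantiomer != "none") paste0("(", x$enantiomer, ")"))
  paste(parts, collapse = "-")
}

#' @export
print.species_label <- function(x, ...) {
  cat(format(x), sprintf("[%s]\n", x$molecule))
  invisible(x)
}

# Compact conformer label for table rows, e.g. "delta-trans-doublet".
conformer_label <- function(site, stereopath, multiplicity) {
  spin <- c(`2` = "doublet", `4` = "quartet", `6` = "sextet")[as.character(multiplicity)]
  ifelse(stereopath %in% c("cis", "trans"),
         paste(site, stereopath, spin, sep = "-"),
         paste(site, spin, sep = "-"))
}

#' Aggregate additive energy corrections
#'
#' The corrected Gibbs free energy used throughout the analysis is the DFT
#' Gibbs energy plus additive terms computed externally: empirical dispersion
#' (D4), geometric counterpoise for basis-set superposition error, and the
#' quasi-harmonic entropy correction; an optional solvent term. The package
#' validates and sums these terms; it never computes them.
#'
#' @param dispersion,bsse,quasi_harmonic,solvent correction terms, hartree.
#' @return A \code{correction_set} object with a \code{total} element.
#' @export
correction_set <- function(dispersion = 0, bsse = 0, quasi_harmonic = 0,
                           solvent = 0) {
  v <- c(dispersion = dispersion, bsse = bsse,
         quasi_harmonic = quasi_harmonic, solvent = solvent)
  if (!all(is.finite(v)))
    stop("all correction terms must be finite numbers")
  structure(c(as.list(v), list(total = sum(v))), class = "correction_set")
}

#' Total corrected free energy
#'
#' Adds a correction set to an electronic-plus-thermal energy. Pure
#' commutative addition in hartree.
#'
#' @param e_plus_thermal energy including thermal contributions, hartree.
#' @param corrections a \code{\link{correction_set}}.
#' @return Corrected energy, hartree.
#' @export
total_free_energy <- function(e_plus_thermal, corrections) {
  if (!inherits(corrections, "correction_set"))
    stop("'corrections' must be a correction_set")
  if (!all(is.finite(e_plus_thermal)))
    stop("'e_plus_thermal' must be finite")
  e_plus_thermal + corrections$total
}

#' Read and write stationary-point tables
#'
#' The on-disk schema is a CSV (or equivalent JSON array of objects) with
#' columns \code{molecule, site, stereopath, enantiomer, multiplicity, stage,
#' e_elec_hartree, h_hartree, g_hartree, dispersion_hartree, bsse_hartree,
#' qh_hartree, solvent_hartree}; empty cells mark absent optional fields.
#' Stages are \code{I} (reactant complex), \code{II} (abstraction TS),
#' \code{III} (radical), \code{IV} (hydroxylated product), or
#' \code{bare-radical}/\code{bare-hydroxylated} for the enzyme-free systems.
#'
#' @param path file path; \code{.json} is detected by extension, anything
#'   else is parsed as CSV.
#' @param points data frame in the schema above.
#' @param validate check the controlled vocabularies and invariants.
#' @return \code{read_stationary_points}: a data frame in the schema.
#' @export
read_stationary_points <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(pin_point_columns, names(df))
  for (m in missing) df[[m]] <- rep(NA, nrow(df))
  df <- df[pin_point_columns]
  num <- grep("_hartree$", names(df), value = TRUE)
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df$multiplicity <- as.integer(df$multiplicity)
  if (validate) assert_points(df)
  df
}

#' @rdname read_stationary_points
#' @export
write_stationary_points <- function(points, path) {
  df <- points[intersect(pin_point_columns, names(points))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

# Hard validation used by readers/constructors; stops on first violation.
assert_points <- function(df) {
  diags <- point_diagnostics(df)
  err <- diags[diags$level == "error", , drop = FALSE]
  if (nrow(err) > 0)
    stop("invalid stationary-point table:\n",
         paste(sprintf("  row %s: %s", err$row, err$message), collapse = "\n"))
  invisible(df)
}

# Shared schema checks returning a diagnostics data frame (row, level, message).
point_diagnostics <- function(df) {
  out <- list()
  add <- function(row, level, message)
    out[[length(out) + 1]] <<- data.frame(row = row, level = level,
                                          message = message)
  if (nrow(df) == 0) {
    add(NA_integer_, "error", "no records")
    return(do.call(rbind, out))
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.na(r$molecule) && !r$molecule %in% pin_molecules)
      add(i, "error", paste0("unknown molecule '", r$molecule, "'"))
    if (!is.na(r$site) && !r$site %in% pin_sites)
      add(i, "error", paste0("unknown site '", r$site, "'"))
    if (!is.na(r$stereopath) && !r$stereopath %in% pin_stereopaths)
      add(i, "error", paste0("unknown stereopath '", r$stereopath, "'"))
    if (!is.na(r$multiplicity) && !r$multiplicity %in% pin_multiplicities)
      add(i, "error", paste0("multiplicity must be 2, 4 or 6, got ",
                             r$multiplicity))
    if (!is.na(r$stage) && !r$stage %in% pin_stages)
      add(i, "error", paste0("unknown stage '", r$stage, "'"))
    if (is.na(r$g_hartree) || !is.finite(r$g_hartree))
      add(i, "error", "g_hartree missing or non-finite")
    if (!is.na(r$stereopath) && r$stereopath %in% c("cis", "trans") &&
        !is.na(r$molecule) && !is.na(r$site) &&
        !identical(r$site, pin_stereo_sites[[r$molecule]]) &&
        !identical(r$stage, "bare-hydroxylated"))
      add(i, "warning",
          paste0("stereopath '", r$stereopath, "' on site '", r$site,
                 "' of ", r$molecule,
                 ": only the site with two diastereotopic allylic H is expected"))
  }
  key <- do.call(paste, c(df[c("molecule", "site", "stereopath", "enantiomer",
                               "multiplicity", "stage")], sep = "|"))
  dup <- which(duplicated(key))
  for (i in dup) add(i, "error", "duplicate (label, stage) record")
  if (length(out) == 0)
    data.frame(row = integer(), level = character(), message = character())
  else do.call(rbind, out)
}

#' Relative energies with respect to a reference structure
#'
#' Converts a set of (corrected) Gibbs free energies in hartree to energies in
#' kcal/mol relative to a reference. With \code{reference = "auto"} the most
#' stable structure (minimum g; first occurrence wins ties) defines the zero,
#' so the minimum maps to exactly 0 and all other values are non-negative —
#' the convention of the published relative-energy tables.
#'
#' @param points a data frame with a \code{g_hartree} column (a bare numeric
#'   vector is also accepted).
#' @param reference \code{"auto"} or the label (row name / \code{label}
#'   column value) of the reference structure.
#' @param labels optional character vector of row labels.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Data frame with columns \code{label}, \code{g_hartree},
#'   \code{rel_kcal}.
#' @examples
#' relative_energies(c(a = -389.823321, b = -389.788789))
#' @export
relative_energies <- function(points, reference = "auto", labels = NULL,
                              constants = pin_constants()) {
  if (is.data.frame(points)) {
    g <- points$g_hartree
    if (is.null(labels))
      labels <- if (!is.null(points$label)) points$label
                else if (all(c("site", "stereopath", "multiplicity") %in% names(points)))
                  conformer_label(points$site, points$stereopath, points$multiplicity)
                else as.character(seq_along(g))
  } else {
    g <- as.numeric(points)
    if (is.null(labels))
      labels <- if (!is.null(names(points))) names(points)
                else as.character(seq_along(g))
  }
  if (length(g) == 0) stop("empty set of stationary points")
  if (!all(is.finite(g))) stop("all g values must be finite")
  if (identical(reference, "auto")) {
    g_ref <- g[which.min(g)]   # first occurrence wins ties
  } else {
    idx <- match(reference, labels)
    if (is.na(idx)) stop("reference label '", reference, "' not found")
    g_ref <- g[idx]
  }
  data.frame(label = labels, g_hartree = g,
             rel_kcal = convert_energy(g - g_ref, "hartree", "kcal/mol",
                                       constants),
             stringsAsFactors = FALSE)
}
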