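# Packaged reference data: the published stationary-point, population and
# descriptor tables of the pinene/CYP multistate study, shipped as CSV with a
# JSON manifest. Values are stored verbatim (ASCII minus signs); printed
# kcal/mol and percentage columns are kept as character strings so that their
# printed precision is recoverable.

reference_set_names <- c("alpha_bare", "beta_bare", "rs_coordinates",
                         "beta_descriptors", "beta_coordI", "beta_coordIII",
                         "alpha_descriptors", "alpha_coordI", "alpha_coordIII")

#' Manifest of the packaged reference tables
#'
#' @return Named list: for each reference set its file name, source table
#'   number, row count, description, and any data-quality notes (the
#'   coordinate-I alpha-pinene set carries one row tagged suspect, whose
#'   printed G value is inconsistent with its printed population).
#' @export
reference_manifest <- function() {
  jsonlite::fromJSON(system.file("extdata", "manifest.json",
                                 package = "pinetics"),
                     simplifyVector = FALSE)
}

#' Load a packaged reference table
#'
#' Returns one of the published tables for the pinene/CYP system as a typed
#' data frame. Conformer ensemble sets (\code{*_coordI}, \code{*_coordIII})
#' carry \code{g_hartree} plus the printed mole fractions/percentages
#' (character, preserving printed precision, with numeric twins
#' \code{printed_fraction_num}/\code{printed_percent_num}) and a
#' \code{suspect} flag. Bare-system sets (\code{*_bare}) carry
#' \code{g_hartree} and the printed relative kcal/mol cell. Descriptor sets
#' (\code{*_descriptors}) carry the nine kinetic/thermodynamic descriptors in
#' kcal/mol.
#'
#' @param name one of \code{alpha_bare}, \code{beta_bare},
#'   \code{rs_coordinates}, \code{beta_descriptors}, \code{beta_coordI},
#'   \code{beta_coordIII}, \code{alpha_descriptors}, \code{alpha_coordI},
#'   \code{alpha_coordIII}.
#' @return Data frame with attributes \code{reference_name},
#'   \code{source_table}, \code{description}.
#' @examples
#' head(load_reference_set("beta_coordIII"))
#' @export
load_reference_set <- function(name) {
  if (!name %in% reference_set_names)
    stop("unknown reference set '", name, "'; available: ",
         paste(reference_set_names, collapse = ", "))
  man <- reference_manifest()[[name]]
  path <- system.file("extdata", man$file, package = "pinetics")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (nm in intersect(c("g_hartree", "g_ref_kcal", "d_r_e", "de_act",
                         "d_r_h", "dh_act", "d_r_g", "dg_act", "d_r_g_cor",
                         "dg_act_cor", "hyd_d_r_g_cor"), names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  for (nm in intersect(c("multiplicity", "coordinate"), names(df)))
    df[[nm]] <- as.integer(df[[nm]])
  if ("suspect" %in% names(df)) df$suspect <- as.logical(df$suspect)
  if ("printed_fraction" %in% names(df))
    df$printed_fraction_num <- as.numeric(df$printed_fraction)
  if ("printed_percent" %in% names(df))
    df$printed_percent_num <- as.numeric(df$printed_percent)
  if (all(c("site", "stereopath", "multiplicity") %in% names(df)))
    df$label <- conformer_label(df$site, df$stereopath, df$multiplicity)
  structure(df, reference_name = name, source_table = man$table,
            description = man$description)
}

#' Compare published Boltzmann populations with recomputation
#'
#' Recomputes the Boltzmann distribution of a packaged conformer ensemble
#' from its G (hartree) column and sets it against the printed mole
#' fractions. Because one printed row of the coordinate-I alpha-pinene set is
#' internally inconsistent (its G implies a negligible weight while a 20.9
#' percent population is printed), comparisons are reported as pairwise
#' population ratios against the most stable non-suspect row, which are
#' immune to the normalisation error such a row introduces.
#'
#' @param name a \code{*_coordI}/\code{*_coordIII} reference-set name, or a
#'   data frame in the same layout.
#' @param temperature K.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Data frame with columns \code{label}, \code{g_hartree},
#'   \code{suspect}, \code{printed_percent}, \code{recomputed_percent},
#'   \code{printed_ratio}, \code{recomputed_ratio}, \code{ratio_rel_err}
#'   (NA where the printed fraction is 0 or the row is suspect).
#' @export
compare_populations <- function(name, temperature = 298.15,
                                constants = pin_constants()) {
  df <- if (is.data.frame(name)) name else load_reference_set(name)
  if (!all(c("g_hartree", "printed_fraction_num") %in% names(df)))
    stop("not a conformer ensemble table")
  pop <- boltzmann_populations(df, temperature, constants)
  ok <- !df$suspect & df$printed_fraction_num > 0
  ref <- which(ok)[which.min(df$g_hartree[ok])]
  printed_ratio <- ifelse(ok, df$printed_fraction_num /
                            df$printed_fraction_num[ref], NA_real_)
  recomputed_ratio <- ifelse(ok, pop$mole_fraction / pop$mole_fraction[ref],
                             NA_real_)
  data.frame(label = df$label, g_hartree = df$g_hartree,
             suspect = df$suspect,
             printed_percent = df$printed_percent_num,
             recomputed_percent = pop$percent,
             printed_ratio = printed_ratio,
             recomputed_ratio = recomputed_ratio,
             ratio_rel_err = recomputed_ratio / printed_ratio - 1,
             stringsAsFactors = FALSE)
}
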