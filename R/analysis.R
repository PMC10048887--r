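# Run configuration and the end-to-end analysis bundling the modules:
# reference tables -> Boltzmann populations at coordinates I and III ->
# descriptor report -> profile diagram.

#' Run configuration
#'
#' All tunable physical and reporting parameters in one serializable object.
#' Defaults reproduce the published analysis: T = 298.15 K, 1 atm,
#' hartree-to-kcal/mol factor 627.5095, quasi-harmonic parameters
#' nu0 = 100 cm^-1, alpha = 4, b_av = 1e-44 kg m^2.
#'
#' @param temperature K. @param pressure atm.
#' @param conversion_constant kcal/mol per hartree.
#' @param nu0,alpha,b_av quasi-harmonic entropy parameters.
#' @param output_precision significant digits for human-readable report
#'   cells (machine-readable outputs always keep full precision).
#' @param seed integer seed for any stochastic step.
#' @param log_level \code{"quiet"}, \code{"info"} or \code{"debug"};
#'   messages go to standard error, never into data streams.
#' @return A \code{run_config} object.
#' @export
run_config <- function(temperature = 298.15, pressure = 1,
                       conversion_constant = 627.5095,
                       nu0 = 100, alpha = 4, b_av = 1e-44,
                       output_precision = 3L, seed = 1L,
                       log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  if (any(c(temperature, pressure, conversion_constant, nu0, alpha, b_av) <= 0))
    stop("all physical parameters must be positive")
  structure(list(temperature = temperature, pressure = pressure,
                 conversion_constant = conversion_constant,
                 nu0 = nu0, alpha = alpha, b_av = b_av,
                 output_precision = as.integer(output_precision),
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path file path (\code{.json} parsed as JSON, otherwise YAML).
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

config_constants <- function(config) {
  pin_constants(hartree_to_kcal = config$conversion_constant,
                default_temperature = config$temperature,
                default_pressure = config$pressure)
}

pin_log <- function(config, level, ...) {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[config$log_level]] >= ranks[[level]])
    message("[pinetics] ", ...)
}

#' End-to-end multistate analysis for one pinene
#'
#' Runs the complete published workflow for the chosen substrate from the
#' packaged reference tables: Boltzmann populations of the reactant-complex
#' conformers (coordinate I) and of the post-abstraction radical conformers
#' (coordinate III), the nine-descriptor kinetic/thermodynamic report over
#' all site/spin/stereopath paths, Eyring rate constants for each corrected
#' barrier, and the reaction-profile diagram anchored at the most stable
#' stage-I structure. Deterministic: identical configuration gives identical
#' output.
#'
#' @param molecule \code{"beta-pinene"} or \code{"alpha-pinene"}.
#' @param config a \code{\link{run_config}}.
#' @return A \code{pinetics_analysis} list: \code{molecule},
#'   \code{populations_I}, \code{populations_III} (population tables),
#'   \code{report} (descriptor data frame with an Eyring \code{k_s} column),
#'   \code{diagram} (see \code{\link{render_diagram}}), \code{config}.
#' @examples
#' res <- run_analysis("beta-pinene")
#' res$populations_III
#' @export
run_analysis <- function(molecule = c("beta-pinene", "alpha-pinene"),
                         config = run_config()) {
  molecule <- match.arg(molecule)
  stopifnot(inherits(config, "run_config"))
  cst <- config_constants(config)
  pre <- if (molecule == "beta-pinene") "beta" else "alpha"
  pin_log(config, "info", "analysis for ", molecule, " at T = ",
          config$temperature, " K")
  coordI <- load_reference_set(paste0(pre, "_coordI"))
  coordIII <- load_reference_set(paste0(pre, "_coordIII"))
  pop_I <- boltzmann_populations(ensemble(coordI, "I", config$temperature),
                                 constants = cst)
  pop_III <- boltzmann_populations(ensemble(coordIII, "III", config$temperature),
                                   constants = cst)
  paths <- reference_paths(molecule, cst)
  report <- suppressWarnings(profile_report(paths, constants = cst))
  report$k_s <- eyring_rate_constant(report$dG_act_cor, config$temperature,
                                     constants = cst)
  diagram <- render_diagram(paths, format = "csv", constants = cst)
  structure(list(molecule = molecule, populations_I = pop_I,
                 populations_III = pop_III, report = report,
                 diagram = diagram, config = config),
            class = "pinetics_analysis")
}

#' @export
print.pinetics_analysis <- function(x, ...) {
  cat("Multistate CYP hydroxylation analysis:", x$molecule, "\n\n")
  cat("-- Reactant-complex conformers (coordinate I) --\n")
  print(x$populations_I)
  cat("\n-- Radical conformers after H abstraction (coordinate III) --\n")
  print(x$populations_III)
  cat("\n-- Kinetic/thermodynamic descriptors (kcal/mol; k in 1/s) --\n")
  rep <- x$report
  num <- vapply(rep, is.numeric, logical(1))
  rep[num] <- lapply(rep[num], signif, x$config$output_precision)
  print(rep, row.names = FALSE)
  ref <- x$diagram$reference_label
  cat(sprintf("\nProfile reference (0 kcal/mol): %s stage-I structure\n",
              conformer_label(ref$site, ref$stereopath, ref$multiplicity)))
  invisible(x)
}

#' Write an analysis bundle to a directory
#'
#' Emits \code{populations_I.csv}, \code{populations_III.csv},
#' \code{report.csv}, \code{diagram.csv} and \code{diagram.svg}, all at full
#' precision. Byte-identical across reruns with the same inputs.
#'
#' @param x a \code{\link{run_analysis}} result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "pinetics_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("populations_I.csv", "populations_III.csv",
                        "report.csv", "diagram.csv", "diagram.svg"))
  utils::write.csv(as.data.frame(x$populations_I), f[1], row.names = FALSE)
  utils::write.csv(as.data.frame(x$populations_III), f[2], row.names = FALSE)
  utils::write.csv(x$report, f[3], row.names = FALSE)
  utils::write.csv(x$diagram$series, f[4], row.names = FALSE)
  cst <- config_constants(x$config)
  paths <- reference_paths(x$molecule, cst)
  render_diagram(paths, "svg", file = f[5], constants = cst)
  invisible(f)
}

#' Validate a stationary-point table file
#'
#' Checks a CSV/JSON stationary-point table against the schema: controlled
#' vocabularies (molecule, site, stereopath, stage), multiplicity in
#' \{2, 4, 6\}, finite free energies, duplicate (label, stage) records,
#' stereopaths only on sites with two diastereotopic allylic hydrogens
#' (warning), and stage-I presence for any path contributing stages II-IV.
#'
#' @param path file path.
#' @return Data frame of diagnostics with columns \code{row} (1-based data
#'   row), \code{level} (\code{"error"}/\code{"warning"}), \code{message};
#'   zero rows means a clean table. Attribute \code{ok} is TRUE iff no
#'   error-level diagnostic.
#' @export
validate_input_table <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  df <- tryCatch(read_stationary_points(path, validate = FALSE),
                 error = function(e) e)
  if (inherits(df, "error")) {
    d <- data.frame(row = NA_integer_, level = "error",
                    message = conditionMessage(df))
    return(structure(d, ok = FALSE))
  }
  d <- point_diagnostics(df)
  if (nrow(df) > 0) {
    grp <- do.call(paste, c(df[c("molecule", "site", "stereopath",
                                 "enantiomer", "multiplicity")], sep = "|"))
    for (g in unique(grp[df$stage %in% c("II", "III", "IV")])) {
      if (!"I" %in% df$stage[grp == g])
        d <- rbind(d, data.frame(
          row = which(grp == g)[1], level = "error",
          message = "stages II-IV present without a stage-I reactant complex"))
    }
  }
  structure(d, ok = !any(d$level == "error"))
}
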