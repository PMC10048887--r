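# Reaction-coordinate assembly: reactant complex (I) -> hydrogen-abstraction
# TS (II) -> substrate radical + Fe-OH (III) -> rebound hydroxylated product
# (IV), per site / spin state / stereopath. The rebound step carries no TS at
# the underlying level of theory, so III -> IV is a first-class barrierless
# segment, never an error.

correction_cols <- c("dispersion_hartree", "bsse_hartree", "qh_hartree",
                     "solvent_hartree")

# Corrected G of each row: g + sum of present correction terms.
point_gcor <- function(df) {
  corr <- rowSums(as.matrix(df[intersect(correction_cols, names(df))]),
                  na.rm = TRUE)
  if (length(corr) == 0) corr <- 0
  df$g_hartree + corr
}

#' Assemble a reaction path from stationary points
#'
#' Collects the stationary points of one site/spin/stereopath path, keyed by
#' reaction-coordinate stage. Stage I is mandatory; a missing abstraction TS
#' (II) or product (IV) is permitted and flagged. The rebound segment
#' (III to IV) is always flagged barrierless: no rebound TS exists in the
#' schema, matching its absence at the underlying level of theory.
#'
#' @param points data frame of stationary points sharing one species label
#'   (same molecule, site, stereopath, enantiomer, multiplicity), one row per
#'   stage among I, II, III, IV.
#' @param note optional free-text annotation (e.g. non-classical sextet
#'   product geometry).
#' @return A \code{reaction_path}: list with \code{label}, \code{stages}
#'   (named list of single-row data frames), \code{barrierless} (named
#'   logical for \code{abstraction} and \code{rebound}), \code{note}.
#' @export
assemble_path <- function(points, note = NULL) {
  if (!is.data.frame(points) || nrow(points) == 0)
    stop("'points' must be a nonempty data frame")
  lab_cols <- intersect(c("molecule", "site", "stereopath", "enantiomer",
                          "multiplicity"), names(points))
  key <- unique(points[lab_cols])
  if (nrow(key) > 1)
    stop("stationary points carry mixed species labels")
  stages <- points$stage
  if (anyDuplicated(stages))
    stop("duplicate stage(s): ",
         paste(unique(stages[duplicated(stages)]), collapse = ", "))
  bad <- setdiff(stages, c("I", "II", "III", "IV"))
  if (length(bad) > 0)
    stop("stages outside the reaction coordinate: ", paste(bad, collapse = ", "))
  if (!"I" %in% stages) stop("stage I (reactant complex) is required")
  stage_list <- lapply(stages, function(s) points[points$stage == s, , drop = FALSE])
  names(stage_list) <- stages
  stage_list <- stage_list[intersect(c("I", "II", "III", "IV"), names(stage_list))]
  structure(list(
    label = as.list(key),
    stages = stage_list,
    barrierless = c(abstraction = !"II" %in% stages, rebound = TRUE),
    note = note
  ), class = "reaction_path")
}

#' @export
print.reaction_path <- function(x, ...) {
  lb <- x$label
  cat(sprintf("Reaction path: %s %s (stages %s)\n",
              if (!is.null(lb$molecule)) lb$molecule else "",
              conformer_label(lb$site, if (is.null(lb$stereopath)) "none" else lb$stereopath,
                              lb$multiplicity),
              paste(names(x$stages), collapse = " -> ")))
  if (x$barrierless["abstraction"])
    cat("  abstraction segment barrierless-flagged (no TS supplied)\n")
  cat("  rebound segment barrierless (no rebound TS at this level)\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

path_stage_col <- function(path, stage, col) {
  st <- path$stages[[stage]]
  if (is.null(st) || !col %in% names(st)) return(NA_real_)
  as.numeric(st[[col]][1])
}

#' Kinetic and thermodynamic descriptors of one reaction path
#'
#' Computes, in kcal/mol, the nine descriptors of the published profile
#' tables: reaction energies (stage III minus stage I) and barriers (stage II
#' minus stage I) in the electronic, enthalpic, Gibbs and corrected-Gibbs
#' columns, plus the hydroxylation free energy (stage IV minus stage I in
#' corrected G). Negative values mean energy released. A descriptor whose
#' energy column is absent comes back NA; the others are still computed.
#'
#' @param path a \code{\link{assemble_path}} result.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Named numeric vector of class \code{path_descriptors} with
#'   elements \code{d_r_e, de_act, d_r_h, dh_act, d_r_g, dg_act, d_r_g_cor,
#'   dg_act_cor, hyd_d_r_g_cor} and attribute \code{label}.
#' @export
path_descriptors <- function(path, constants = pin_constants()) {
  if (!inherits(path, "reaction_path")) stop("'path' must be a reaction_path")
  C <- constants$hartree_to_kcal
  delta <- function(col, a, b) {
    va <- path_stage_col(path, a, col); vb <- path_stage_col(path, b, col)
    (va - vb) * C
  }
  gcor <- function(stage) {
    st <- path$stages[[stage]]
    if (is.null(st)) return(NA_real_)
    unname(point_gcor(st)[1])
  }
  out <- c(
    d_r_e = delta("e_elec_hartree", "III", "I"),
    de_act = delta("e_elec_hartree", "II", "I"),
    d_r_h = delta("h_hartree", "III", "I"),
    dh_act = delta("h_hartree", "II", "I"),
    d_r_g = delta("g_hartree", "III", "I"),
    dg_act = delta("g_hartree", "II", "I"),
    d_r_g_cor = (gcor("III") - gcor("I")) * C,
    dg_act_cor = (gcor("II") - gcor("I")) * C,
    hyd_d_r_g_cor = (gcor("IV") - gcor("I")) * C
  )
  structure(out, class = "path_descriptors", label = path$label)
}

#' @export
print.path_descriptors <- function(x, ...) {
  lb <- attr(x, "label")
  cat("Path descriptors (kcal/mol) for",
      conformer_label(lb$site, if (is.null(lb$stereopath)) "none" else lb$stereopath,
                      lb$multiplicity), "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Profile report over a set of reaction paths
#'
#' One row per (site, spin, stereopath) path with the nine descriptors of
#' \code{\link{path_descriptors}}, ordered by site (first appearance), then
#' spin ascending, then cis before trans — the layout of the published
#' kinetic/thermodynamic tables. Transition-state betweenness (corrected G of
#' the TS above both stage I and stage III) is checked and violations are
#' reported as warnings, since the published set itself contains one
#' endergonic path whose barrier lies below the reaction energy.
#'
#' @param paths list of \code{reaction_path} objects.
#' @param warn_ts warn on transition-state betweenness violations.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Data frame with columns \code{site, spin, stereopath, enantiomer,
#'   dE_r, dE_act, dH_r, dH_act, dG_r, dG_act, dG_r_cor, dG_act_cor,
#'   hyd_dG_r_cor}.
#' @export
profile_report <- function(paths, warn_ts = TRUE,
                           constants = pin_constants()) {
  if (inherits(paths, "reaction_path")) paths <- list(paths)
  if (length(paths) == 0) stop("at least one reaction path is required")
  rows <- lapply(paths, function(p) {
    d <- path_descriptors(p, constants)
    lb <- p$label
    data.frame(site = lb$site,
               spin = lb$multiplicity,
               stereopath = if (is.null(lb$stereopath)) "none" else lb$stereopath,
               enantiomer = if (is.null(lb$enantiomer)) "none" else lb$enantiomer,
               dE_r = d[["d_r_e"]], dE_act = d[["de_act"]],
               dH_r = d[["d_r_h"]], dH_act = d[["dh_act"]],
               dG_r = d[["d_r_g"]], dG_act = d[["dg_act"]],
               dG_r_cor = d[["d_r_g_cor"]], dG_act_cor = d[["dg_act_cor"]],
               hyd_dG_r_cor = d[["hyd_d_r_g_cor"]],
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  site_rank <- match(rep$site, unique(rep$site))
  stereo_rank <- match(rep$stereopath, c("cis", "trans", "none"))
  rep <- rep[order(site_rank, rep$spin, stereo_rank), , drop = FALSE]
  rownames(rep) <- NULL
  if (warn_ts) {
    viol <- !is.na(rep$dG_act_cor) & !is.na(rep$dG_r_cor) &
      (rep$dG_act_cor < 0 | rep$dG_act_cor < rep$dG_r_cor)
    if (any(viol))
      warning("abstraction TS not between stages I and III in corrected G for: ",
              paste(conformer_label(rep$site[viol], rep$stereopath[viol],
                                    rep$spin[viol]), collapse = ", "))
  }
  rep
}

#' Reaction-profile diagram relative to the global reference
#'
#' Anchors every path of a profile at the single global reference — the most
#' stable stage-I structure (minimum corrected G) across all paths — and
#' emits stage-wise relative energies in kcal/mol, the convention of the
#' published reaction-coordinate figures. Stages are evenly spaced on the
#' abscissa.
#'
#' @param paths list of \code{reaction_path} objects (or one).
#' @param format \code{"csv"}, \code{"text"} or \code{"svg"}.
#' @param file optional output file; the rendering is also returned.
#' @param constants a \code{\link{pin_constants}} object.
#' @return Invisibly, a list with \code{reference_label} (label list of the
#'   reference structure), \code{series} (data frame \code{path, stage,
#'   stage_index, rel_kcal}) and \code{rendering} (character for text/svg,
#'   the series data frame for csv).
#' @export
render_diagram <- function(paths, format = c("csv", "text", "svg"),
                           file = NULL, constants = pin_constants()) {
  format <- match.arg(format)
  if (inherits(paths, "reaction_path")) paths <- list(paths)
  if (length(paths) == 0) stop("at least one reaction path is required")
  g_I <- vapply(paths, function(p) point_gcor(p$stages[["I"]])[1], numeric(1))
  ref_idx <- which.min(g_I)
  g_ref <- g_I[ref_idx]
  series <- do.call(rbind, lapply(paths, function(p) {
    lb <- p$label
    stages <- names(p$stages)
    data.frame(
      path = conformer_label(lb$site,
                             if (is.null(lb$stereopath)) "none" else lb$stereopath,
                             lb$multiplicity),
      stage = stages,
      stage_index = match(stages, c("I", "II", "III", "IV")),
      rel_kcal = vapply(stages, function(s)
        (point_gcor(p$stages[[s]])[1] - g_ref) * constants$hartree_to_kcal,
        numeric(1)),
      stringsAsFactors = FALSE)
  }))
  rownames(series) <- NULL
  rendering <- switch(format,
    csv = series,
    text = diagram_text(series),
    svg = diagram_svg(series))
  if (!is.null(file)) {
    if (format == "csv") utils::write.csv(series, file, row.names = FALSE)
    else writeLines(rendering, file)
  }
  invisible(list(reference_label = paths[[ref_idx]]$label, series = series,
                 rendering = rendering))
}

diagram_text <- function(series) {
  lines <- c("Reaction profile (kcal/mol, relative to most stable stage-I structure)",
             sprintf("%-28s %5s %12s", "path", "stage", "rel_kcal"))
  for (i in seq_len(nrow(series)))
    lines <- c(lines, sprintf("%-28s %5s %12.4f", series$path[i],
                              series$stage[i], series$rel_kcal[i]))
  lines
}

# Minimal deterministic static SVG: one polyline per path, horizontal level
# bars at each stage.
diagram_svg <- function(series, width = 640, height = 420, margin = 50) {
  rng <- range(series$rel_kcal)
  if (diff(rng) == 0) rng <- rng + c(-1, 1)
  xs <- function(i) margin + (i - 1) / 3 * (width - 2 * margin)
  ys <- function(v) height - margin -
    (v - rng[1]) / diff(rng) * (height - 2 * margin)
  paths <- unique(series$path)
  cols <- grDevices::hcl(h = seq(15, 375, length.out = length(paths) + 1)[seq_along(paths)],
                         c = 80, l = 45)
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           '<rect width="100%" height="100%" fill="white"/>')
  for (k in seq_along(paths)) {
    s <- series[series$path == paths[k], , drop = FALSE]
    s <- s[order(s$stage_index), , drop = FALSE]
    pts <- sprintf("%.2f,%.2f", xs(s$stage_index), ys(s$rel_kcal))
    out <- c(out,
      sprintf('<polyline fill="none" stroke="%s" stroke-width="1.5" points="%s"/>',
              cols[k], paste(pts, collapse = " ")),
      sprintf('<text x="%.2f" y="%.2f" font-size="9" fill="%s">%s</text>',
              xs(s$stage_index[1]) + 4, ys(s$rel_kcal[1]) - 4, cols[k], paths[k]))
    for (i in seq_len(nrow(s)))
      out <- c(out, sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="3"/>',
                            xs(s$stage_index[i]) - 12, ys(s$rel_kcal[i]),
                            xs(s$stage_index[i]) + 12, ys(s$rel_kcal[i]), cols[k]))
  }
  for (i in 1:4)
    out <- c(out, sprintf('<text x="%.2f" y="%.2f" font-size="11" text-anchor="middle">%s</text>',
                          xs(i), height - margin / 2, c("I", "II", "III", "IV")[i]))
  c(out, "</svg>")
}

#' Reaction paths reconstructed from the packaged reference tables
#'
#' Builds the full multistate path set for one pinene from the packaged
#' coordinate-I ensemble and descriptor tables. Only stage-I absolute Gibbs
#' energies are published; stages II, III and IV are therefore reconstructed
#' as stage-I G plus the corresponding printed descriptor (barrier, reaction
#' energy, hydroxylation energy), and the paths are flagged
#' \code{reconstructed}. Electronic and enthalpic columns share the stage-I G
#' anchor (absolute anchors are arbitrary; only stage differences are
#' meaningful). The gap between corrected and uncorrected descriptors is
#' carried as a lumped correction term on stages II and III.
#'
#' @param molecule \code{"alpha-pinene"} or \code{"beta-pinene"}.
#' @param constants a \code{\link{pin_constants}} object.
#' @return List of \code{reaction_path} objects with attribute
#'   \code{reconstructed = TRUE}.
#' @export
reference_paths <- function(molecule = c("beta-pinene", "alpha-pinene"),
                            constants = pin_constants()) {
  molecule <- match.arg(molecule)
  pre <- if (molecule == "beta-pinene") "beta" else "alpha"
  desc <- load_reference_set(paste0(pre, "_descriptors"))
  coordI <- load_reference_set(paste0(pre, "_coordI"))
  C <- constants$hartree_to_kcal
  paths <- lapply(seq_len(nrow(desc)), function(i) {
    d <- desc[i, ]
    j <- which(coordI$site == d$site & coordI$stereopath == d$stereopath &
                 coordI$multiplicity == d$multiplicity)
    if (length(j) != 1)
      stop("no unique coordinate-I match for ",
           conformer_label(d$site, d$stereopath, d$multiplicity))
    gI <- coordI$g_hartree[j]
    mk <- function(stage, e, h, g, lump) {
      data.frame(molecule = molecule, site = d$site, stereopath = d$stereopath,
                 enantiomer = d$enantiomer, multiplicity = d$multiplicity,
                 stage = stage, e_elec_hartree = e, h_hartree = h,
                 g_hartree = g, dispersion_hartree = lump,
                 bsse_hartree = 0, qh_hartree = 0, solvent_hartree = 0,
                 stringsAsFactors = FALSE)
    }
    pts <- rbind(
      mk("I", gI, gI, gI, 0),
      mk("II", gI + d$de_act / C, gI + d$dh_act / C, gI + d$dg_act / C,
         (d$dg_act_cor - d$dg_act) / C),
      mk("III", gI + d$d_r_e / C, gI + d$d_r_h / C, gI + d$d_r_g / C,
         (d$d_r_g_cor - d$d_r_g) / C),
      mk("IV", NA_real_, NA_real_, gI + d$hyd_d_r_g_cor / C, 0)
    )
    p <- assemble_path(pts)
    attr(p, "reconstructed") <- TRUE
    p
  })
  paths
}
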