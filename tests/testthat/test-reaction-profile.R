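# Reaction-path assembly, descriptors, reports and diagrams.

synthetic_path <- function(gI = 0, gII = 0.02, gIII = -0.01, gIV = NULL,
                           site = "delta", stereopath = "trans", mult = 2L) {
  stages <- c("I", "II", "III", if (!is.null(gIV)) "IV")
  g <- c(gI, gII, gIII, gIV)
  assemble_path(data.frame(
    molecule = "beta-pinene", site = site, stereopath = stereopath,
    enantiomer = "S", multiplicity = mult, stage = stages,
    e_elec_hartree = g, h_hartree = g, g_hartree = g,
    dispersion_hartree = 0, bsse_hartree = 0, qh_hartree = 0,
    solvent_hartree = 0, stringsAsFactors = FALSE))
}

test_that("path assembly validates stages and flags barrierless segments", {
  p <- synthetic_path(gIV = -0.08)
  expect_s3_class(p, "reaction_path")
  expect_false(p$barrierless[["abstraction"]])
  expect_true(p$barrierless[["rebound"]])  # no rebound TS in the schema
  # missing TS is a state, not an error
  p2 <- assemble_path(data.frame(site = "delta", stereopath = "trans",
                                 multiplicity = 2L, stage = c("I", "III"),
                                 g_hartree = c(0, -0.01)))
  expect_true(p2$barrierless[["abstraction"]])
  expect_error(assemble_path(data.frame(site = "delta", stage = c("II", "III"),
                                        g_hartree = c(1, 2))),
               "stage I")
  expect_error(assemble_path(data.frame(site = "delta",
                                        stage = c("I", "II", "II"),
                                        g_hartree = 1:3)),
               "duplicate")
  expect_error(assemble_path(data.frame(site = c("delta", "alpha"),
                                        stage = c("I", "II"),
                                        g_hartree = 1:2)),
               "mixed")
})

test_that("descriptors follow the stage-difference convention", {
  d <- path_descriptors(synthetic_path())
  expect_equal(d[["dg_act"]], 12.55, tolerance = 1e-4)
  expect_equal(d[["d_r_g"]], -6.28, tolerance = 1e-3)
  expect_equal(d[["dg_act_cor"]], d[["dg_act"]])   # zero corrections
  # stage III identical to stage I: all reaction terms zero
  d0 <- path_descriptors(synthetic_path(gIII = 0))
  expect_equal(unname(d0[c("d_r_e", "d_r_h", "d_r_g", "d_r_g_cor")]),
               rep(0, 4))
  # missing energy column: that descriptor NA, others intact
  p <- assemble_path(data.frame(site = "delta", stereopath = "trans",
                                multiplicity = 2L, stage = c("I", "II", "III"),
                                g_hartree = c(0, 0.02, -0.01)))
  d2 <- path_descriptors(p)
  expect_true(is.na(d2[["d_r_e"]]) && is.na(d2[["dh_act"]]))
  expect_equal(d2[["dg_act"]], 12.55, tolerance = 1e-4)
})

test_that("profile report reproduces the published descriptor tables", {
  for (mol in c("beta-pinene", "alpha-pinene")) {
    paths <- reference_paths(mol)
    rep <- suppressWarnings(profile_report(paths))
    name <- paste0(if (mol == "beta-pinene") "beta" else "alpha",
                   "_descriptors")
    tab <- load_reference_set(name)
    key_rep <- paste(rep$site, rep$stereopath, rep$spin)
    key_tab <- paste(tab$site, tab$stereopath, tab$multiplicity)
    m <- match(key_tab, key_rep)
    expect_false(anyNA(m))
    expect_equal(rep$dG_r_cor[m], tab$d_r_g_cor, tolerance = 1e-9)
    expect_equal(rep$dG_act_cor[m], tab$dg_act_cor, tolerance = 1e-9)
    expect_equal(rep$hyd_dG_r_cor[m], tab$hyd_d_r_g_cor, tolerance = 1e-9)
    expect_equal(rep$dE_r[m], tab$d_r_e, tolerance = 1e-9)
    expect_equal(rep$dH_act[m], tab$dh_act, tolerance = 1e-9)
    expect_equal(rep$dG_r[m], tab$d_r_g, tolerance = 1e-9)
  }
  # published spot row: delta trans doublet of the beta-pinene set
  rep <- suppressWarnings(profile_report(reference_paths("beta-pinene")))
  row <- rep[rep$site == "delta" & rep$stereopath == "trans" & rep$spin == 2, ]
  expect_equal(row$dG_r_cor, -8.30)
  expect_equal(row$dG_act_cor, 10.8)
})

test_that("report ordering is site, then spin ascending, then cis first", {
  rep <- suppressWarnings(profile_report(reference_paths("beta-pinene")))
  expect_identical(unique(rep$site), c("delta", "alpha"))
  delta <- rep[rep$site == "delta", ]
  expect_identical(delta$spin, c(2L, 2L, 4L, 4L, 6L, 6L))
  expect_identical(delta$stereopath, rep(c("cis", "trans"), 3))
})

test_that("hydroxylation consistency: hyd - d_r_g_cor equals the III->IV drop", {
  for (mol in c("beta-pinene", "alpha-pinene")) {
    for (p in reference_paths(mol)) {
      d <- path_descriptors(p)
      gIII <- sum(unlist(p$stages[["III"]][c("g_hartree", "dispersion_hartree",
                                             "bsse_hartree", "qh_hartree",
                                             "solvent_hartree")]))
      gIV <- sum(unlist(p$stages[["IV"]][c("g_hartree", "dispersion_hartree",
                                           "bsse_hartree", "qh_hartree",
                                           "solvent_hartree")]))
      expect_equal(d[["hyd_d_r_g_cor"]] - d[["d_r_g_cor"]],
                   (gIV - gIII) * 627.5095, tolerance = 1e-9)
    }
  }
})

test_that("TS betweenness holds on the fixtures except the published outlier", {
  # the endergonic alpha-doublet path of the beta-pinene set has its barrier
  # below the reaction free energy in the published table itself
  expect_warning(profile_report(reference_paths("beta-pinene")),
                 "alpha-doublet")
  expect_silent(rep_a <- profile_report(reference_paths("alpha-pinene")))
  expect_true(all(rep_a$dG_act_cor >= 0))
})

test_that("diagram anchors at the most stable stage-I structure", {
  paths <- reference_paths("beta-pinene")
  dia <- render_diagram(paths, format = "csv")
  # the most stable reactant complex is the alpha-site doublet
  expect_equal(dia$reference_label$site, "alpha")
  expect_equal(dia$reference_label$multiplicity, 2L)
  expect_equal(min(dia$series$rel_kcal[dia$series$stage == "I"]), 0)
  # alpha-pinene: most stable coordinate-I structure is the gamma doublet
  dia_a <- render_diagram(reference_paths("alpha-pinene"), format = "csv")
  expect_equal(dia_a$reference_label$site, "gamma")
  expect_equal(dia_a$reference_label$multiplicity, 2L)
  # flat path renders a flat line at zero
  flat <- synthetic_path(0, 0, 0, 0)
  expect_equal(render_diagram(flat, "csv")$series$rel_kcal, rep(0, 4))
  expect_error(render_diagram(paths, format = "png"))
})

test_that("diagram renderings agree across formats and shifts", {
  paths <- reference_paths("beta-pinene")
  csv <- render_diagram(paths, "csv")
  txt <- render_diagram(paths, "text")
  svg <- render_diagram(paths, "svg")
  expect_equal(csv$series, txt$series)
  expect_equal(csv$series, svg$series)
  # text rendering carries the same numbers
  parsed <- as.numeric(sub(".* ", "", txt$rendering[-(1:2)]))
  expect_equal(parsed, round(csv$series$rel_kcal, 4))
  expect_true(any(grepl("^<svg", svg$rendering)))
  # reference invariance: uniform shift leaves diagram and descriptors alone
  shifted <- lapply(paths, function(p) {
    p$stages <- lapply(p$stages, function(st) {
      st$g_hartree <- st$g_hartree + 3.21
      st$e_elec_hartree <- st$e_elec_hartree + 3.21
      st$h_hartree <- st$h_hartree + 3.21
      st
    })
    p
  })
  expect_equal(render_diagram(shifted, "csv")$series$rel_kcal,
               csv$series$rel_kcal, tolerance = 1e-8)
  expect_equal(unclass(path_descriptors(shifted[[2]])),
               unclass(path_descriptors(paths[[2]])), tolerance = 1e-7)
})

test_that("profile report round-trips through CSV", {
  rep <- suppressWarnings(profile_report(reference_paths("alpha-pinene")))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rep, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$dG_act_cor, rep$dG_act_cor)
  expect_identical(back$stereopath, rep$stereopath)
  unlink(f)
})
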