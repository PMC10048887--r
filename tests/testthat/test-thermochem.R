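# RRHO / quasi-RRHO thermochemistry against independently coded closed-form
# oracles (helper-oracles.R).

test_that("harmonic mode entropy matches the closed-form oracle", {
  expect_equal(rrho_mode_entropy(100, 298.15), 5.504805281305e-06,
               tolerance = 1e-10)
  for (nu in c(10, 50, 100, 500, 1500, 3000))
    for (T in c(150, 298.15, 600))
      expect_equal(rrho_mode_entropy(nu, T), oracle_ho_entropy(nu, T),
                   tolerance = 1e-12)
  # limits and monotonicity
  expect_lt(rrho_mode_entropy(5000, 298.15), 1e-14)
  s <- rrho_mode_entropy(c(50, 100, 200, 400), 298.15)
  expect_true(all(diff(s) < 0))               # decreasing in frequency
  expect_gt(rrho_mode_entropy(100, 2 * 298.15),
            rrho_mode_entropy(100, 298.15))   # increasing in T
  expect_error(rrho_mode_entropy(-10, 298.15), "> 0")
  expect_error(rrho_mode_entropy(100, -1), "> 0")
})

test_that("free-rotor mode entropy matches the oracle and its identities", {
  expect_equal(free_rotor_mode_entropy(50, 298.15, 1e-44),
               5.646346694588e-06, tolerance = 1e-10)
  for (nu in c(20, 50, 100, 300))
    expect_equal(free_rotor_mode_entropy(nu, 298.15, 1e-44),
                 oracle_fr_entropy(nu, 298.15, 1e-44), tolerance = 1e-12)
  # very high nu => mu << b_av => reduced moment ~ unreduced
  cst <- pin_constants()
  nu <- 1e5
  mu <- cst$planck / (8 * pi^2 * cst$speed_of_light * nu)
  s_unreduced <- (0.5 + log(sqrt(8 * pi^3 * mu * cst$boltzmann_si * 298.15) /
                              cst$planck)) * cst$boltzmann_hartree
  expect_equal(free_rotor_mode_entropy(nu, 298.15, 1e-44), s_unreduced,
               tolerance = 1e-3)
  # doubling b_av shifts S by (kB/2) ln(mu2'/mu1') exactly
  B <- 1e-44; nu <- 80
  mu <- cst$planck / (8 * pi^2 * cst$speed_of_light * nu)
  mup1 <- mu * B / (mu + B); mup2 <- mu * 2 * B / (mu + 2 * B)
  expect_equal(free_rotor_mode_entropy(nu, 298.15, 2 * B) -
                 free_rotor_mode_entropy(nu, 298.15, B),
               0.5 * cst$boltzmann_hartree * log(mup2 / mup1),
               tolerance = 1e-9)
  expect_error(free_rotor_mode_entropy(50, 298.15, -1), "> 0")
})

test_that("quasi-harmonic vibrational entropy interpolates mode-wise", {
  freqs <- c(23.7, 48.2, 77.9, 101.5, 140.2, 333.3, 642.1, 1200.8, 1710.4,
             3020.6)
  expect_equal(as.numeric(quasi_rrho_vibrational_entropy(freqs, 298.15)),
               oracle_qrrho_entropy(freqs, 298.15), tolerance = 1e-12)
  # mode-wise envelope between RRHO and free rotor
  pm <- attr(quasi_rrho_vibrational_entropy(freqs, 298.15), "per_mode")
  lo <- pmin(pm$s_rrho, pm$s_fr); hi <- pmax(pm$s_rrho, pm$s_fr)
  expect_true(all(pm$s >= lo - 1e-18 & pm$s <= hi + 1e-18))
  # high-frequency spectrum: quasi-RRHO within 0.01% of pure RRHO
  hf <- seq(2000, 3600, by = 200)
  q <- as.numeric(quasi_rrho_vibrational_entropy(hf, 298.15))
  r <- as.numeric(quasi_rrho_vibrational_entropy(hf, 298.15, method = "RRHO"))
  expect_equal(q, r, tolerance = 1e-4)
  # crossover mode: exact midpoint at nu = nu0
  s <- as.numeric(quasi_rrho_vibrational_entropy(100, 298.15, nu0 = 100))
  mid <- (rrho_mode_entropy(100, 298.15) +
            free_rotor_mode_entropy(100, 298.15, 1e-44)) / 2
  expect_equal(s, mid, tolerance = 1e-18)
  # imaginary modes are dropped with a warning and never contribute
  expect_warning(si <- quasi_rrho_vibrational_entropy(c(-500, freqs), 298.15),
                 "imaginary")
  expect_equal(as.numeric(si),
               as.numeric(quasi_rrho_vibrational_entropy(freqs, 298.15)))
  expect_error(suppressWarnings(quasi_rrho_vibrational_entropy(-100, 298.15)),
               "no positive frequencies")
})

test_that("entropies increase monotonically with temperature", {
  grid <- seq(100, 1000, by = 100)
  freqs <- generate_spectrum(spectrum_spec(15, c(30, 3200), seed = 5))
  sv <- vapply(grid, function(T)
    as.numeric(quasi_rrho_vibrational_entropy(freqs, T)), numeric(1))
  expect_true(all(diff(sv) > 0))
  sf <- vapply(grid, function(T) free_rotor_mode_entropy(60, T), numeric(1))
  expect_true(all(diff(sf) > 0))
})

test_that("full thermochemistry components match textbook oracles (diatomic)", {
  # CO-like toy: one 2143 cm^-1 mode, linear rotor, sigma 1
  tr <- thermochemistry(2143, molar_mass = 28.01,
                        principal_moments = 1.449e-46, linear = TRUE,
                        rotational_symmetry_number = 1,
                        electronic_degeneracy = 1,
                        temperature = 298.15, pressure = 1, method = "RRHO")
  # the oracle converts molar J/(mol K) through Avogadro and the hartree,
  # while the package carries k_B in Eh/K directly; the two constants agree
  # to ~1e-10 relative, which bounds the attainable agreement
  expect_equal(tr$s_trans, oracle_trans_entropy(28.01, 298.15, 1),
               tolerance = 1e-9)
  expect_equal(tr$s_rot, oracle_rot_entropy_linear(1.449e-46, 1, 298.15),
               tolerance = 1e-9)
  expect_equal(tr$s_vib, oracle_ho_entropy(2143, 298.15), tolerance = 1e-12)
  expect_equal(tr$s_elec, 0)   # degeneracy 1 contributes exactly zero
  # ZPE = h c nu / 2 in hartree
  expect_equal(tr$zpe, orc$h * orc$c_cm * 2143 / 2 / orc$Eh_J,
               tolerance = 1e-12)
  # g_corr consistency invariant
  expect_equal(tr$g_corr,
               tr$h_corr - 298.15 * (tr$s_trans + tr$s_rot + tr$s_vib +
                                       tr$s_elec),
               tolerance = 1e-10)
  expect_true(tr$zpe >= 0 && tr$s_trans > 0 && tr$s_rot > 0 && tr$s_vib > 0)
})

test_that("RRHO and quasi-RRHO differ only in the vibrational entropy", {
  freqs <- generate_spectrum(spectrum_spec(12, c(40, 3000), seed = 3))
  a <- thermochemistry(freqs, 136.23, c(3e-45, 4e-45, 6e-45), method = "RRHO")
  b <- thermochemistry(freqs, 136.23, c(3e-45, 4e-45, 6e-45),
                       method = "quasi-RRHO")
  expect_equal(a$zpe, b$zpe)
  expect_equal(a$h_corr, b$h_corr)
  expect_equal(a$s_trans, b$s_trans)
  expect_equal(a$s_rot, b$s_rot)
  expect_false(isTRUE(all.equal(a$s_vib, b$s_vib)))
  # electronic degeneracy contributes k ln g
  c2 <- thermochemistry(freqs, 136.23, c(3e-45, 4e-45, 6e-45),
                        electronic_degeneracy = 2)
  expect_equal(c2$s_elec, pin_constants()$boltzmann_hartree * log(2))
  # appending an imaginary mode leaves every component unchanged
  d <- suppressWarnings(
    thermochemistry(c(freqs, -450), 136.23, c(3e-45, 4e-45, 6e-45),
                    method = "quasi-RRHO"))
  b_cmp <- b; d_cmp <- d
  b_cmp$n_imaginary <- NULL; d_cmp$n_imaginary <- NULL
  expect_equal(d_cmp, b_cmp)
  expect_error(thermochemistry(freqs, -1, c(1e-45, 1e-45, 1e-45)), "> 0")
  expect_error(thermochemistry(freqs, 10, c(-1e-45, 1e-45, 1e-45)), "> 0")
})

test_that("frequency-list files parse with comments and imaginary modes", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# abstraction TS spectrum", "-1512.3", "88.1", "", "240.0",
               "3011.7"), f)
  expect_equal(read_frequencies(f), c(-1512.3, 88.1, 240.0, 3011.7))
  writeLines(c("12.0", "oops"), f)
  expect_error(read_frequencies(f), "non-numeric")
  unlink(f)
})
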