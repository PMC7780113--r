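# Configuration interaction: enumeration, matrix construction against the
# Fock-space oracle, state solving, oscillator strengths.

test_that("configuration enumeration counts and ordering", {
  scf <- fx_h4_scf()
  # toy with 2 occupied x 2 virtual: 4 singles, 8 with paired doubles
  all8 <- enumerate_configurations(scf, n_singles = 4,
                                   include_paired_doubles = TRUE)
  expect_equal(nrow(all8), 8)
  expect_equal(sum(all8$kind == "single"), 4)
  only4 <- enumerate_configurations(scf, n_singles = 4,
                                    include_paired_doubles = FALSE)
  expect_equal(nrow(only4), 4)
  # ranked by ascending zeroth-order gap
  expect_true(all(diff(only4$gap_eV) >= -1e-12))
  # requesting more singles than exist falls back with a warning
  expect_warning(allw <- enumerate_configurations(scf, n_singles = 99,
                                                  include_paired_doubles
                                                  = FALSE),
                 "using all")
  expect_equal(nrow(allw), 4)
  # out-of-range configurations are refused downstream
  bad <- only4
  bad$m[1] <- 99
  expect_error(build_ci_matrix(bad, scf), "consistency")
})

test_that("CI matrix matches the Jordan-Wigner Fock-space oracle", {
  skip_if_not_installed("Matrix")
  scf <- fx_h4_scf()
  configs <- enumerate_configurations(scf, n_singles = 4,
                                      include_paired_doubles = TRUE)
  jw <- jw_hamiltonian(scf)
  Horacle <- jw_csf_matrix(jw, configs, scf$n_occupied)
  singles <- which(configs$kind == "single")
  Horacle[1, 1 + singles] <- Horacle[1 + singles, 1] <- 0  # Brillouin
  Hform <- build_ci_matrix(configs, scf, engine = "formula")
  Hdet <- build_ci_matrix(configs, scf, engine = "determinant")
  expect_lt(max(abs(Hdet - Horacle)), 1e-9)
  expect_lt(max(abs(Hform - Horacle)), 1e-6)
  expect_lt(max(abs(Hform - t(Hform))), 1e-12)
  # ground state couples to paired doubles but not to singles
  doubles <- which(configs$kind == "paired_double")
  expect_gt(max(abs(Hform[1, 1 + doubles])), 1e-3)
  expect_equal(max(abs(Hform[1, 1 + singles])), 0)
})

test_that("full singles-space CIS matches the brute-force determinant
          diagonalization", {
  skip_if_not_installed("Matrix")
  scf <- fx_h4_scf()
  configs <- enumerate_configurations(scf, n_singles = 4,
                                      include_paired_doubles = FALSE)
  H <- build_ci_matrix(configs, scf)
  sol <- solve_states(H)
  jw <- jw_hamiltonian(scf)
  det_evals <- jw_singles_space_energies(jw, scf$n_occupied, scf$n_basis)
  det_exc <- det_evals - det_evals[1]
  # every singlet CIS root appears among the determinant-space roots
  for (e in sol$excitation_energies_eV[sol$excitation_energies_eV > 0]) {
    expect_lt(min(abs(det_exc - e)), 1e-8)
  }
})

test_that("formula and determinant engines agree on an asymmetric
          6-electron toy", {
  h6 <- fragment_geometry(
    data.frame(element = "H", name = paste0("H", 1:6),
               x = c(0, 0.95, 1.9, 2.9, 3.8, 4.7),
               y = c(0, 0.1, 0.6, 1.2, 1.0, 1.6),
               z = c(0, 0, 0.1, 0, 0.2, 0.1)))
  scf <- scf_solve(h6, fx_params_tight())
  configs <- enumerate_configurations(scf, n_singles = 9,
                                      include_paired_doubles = TRUE)
  Hf <- build_ci_matrix(configs, scf, engine = "formula")
  Hd <- build_ci_matrix(configs, scf, engine = "determinant")
  expect_lt(max(abs(Hf - Hd)), 1e-7)
})

test_that("solve_states: Brillouin ground state and variational doubles", {
  scf <- fx_h4_scf()
  cs <- enumerate_configurations(scf, n_singles = 4,
                                 include_paired_doubles = FALSE)
  sol_s <- solve_states(build_ci_matrix(cs, scf))
  # singles-only: CI ground state is the SCF reference exactly
  expect_equal(sol_s$ground_energy_eV, 0, tolerance = 1e-10)
  expect_equal(abs(sol_s$vectors[1, 1]), 1, tolerance = 1e-10)
  cd <- enumerate_configurations(scf, n_singles = 4,
                                 include_paired_doubles = TRUE)
  sol_d <- solve_states(build_ci_matrix(cd, scf))
  # adding paired doubles never raises the ground state
  expect_lte(sol_d$ground_energy_eV, sol_s$ground_energy_eV + 1e-12)
  expect_true(all(sol_d$excitation_energies_eV > 0))
  expect_error(solve_states(matrix(c(0, 1, 2, 0), 2, 2)),
               "not symmetric")
})

test_that("oscillator strengths are non-negative, finite, and
          origin-insensitive", {
  sp <- fx_surrogate_spectrum()
  expect_true(all(sp$states$oscillator_strength >= 0))
  expect_true(is.finite(sum(sp$states$oscillator_strength)))
  expect_gt(sum(sp$states$oscillator_strength), 0)
  # lambda = 1239.842 / E across all states
  expect_equal(sp$states$wavelength_nm,
               1239.842 / sp$states$energy_eV, tolerance = 1e-6)
  # translating the whole fragment leaves f unchanged (dipole origin)
  s <- fx_surrogate()
  moved <- s$fragment
  moved$atoms$x <- moved$atoms$x + 7.3
  moved$atoms$y <- moved$atoms$y - 2.1
  sp2 <- compute_spectrum(moved, fx_params(), n_singles = 40,
                          n_states = 10)
  expect_equal(sp$states$oscillator_strength,
               sp2$states$oscillator_strength, tolerance = 1e-6)
  # H2 sanity: the sigma->sigma* transition along the bond is bright
  h2 <- fragment_geometry(data.frame(element = "H",
                                     name = c("H1", "H2"),
                                     x = c(0, 0.74), y = 0, z = 0))
  sph2 <- compute_spectrum(h2, fx_params(), n_singles = 1,
                           include_paired_doubles = FALSE)
  expect_gt(sph2$states$oscillator_strength[1], 0.1)
})

test_that("spectrum export round-trips", {
  sp <- fx_surrogate_spectrum()
  f <- tempfile(fileext = ".tsv")
  export_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(nrow(back), nrow(sp$states))
  expect_equal(back$wavelength_nm, sp$states$wavelength_nm,
               tolerance = 1e-9)
  expect_equal(back$oscillator_strength,
               sp$states$oscillator_strength, tolerance = 1e-9)
  expect_true(all(diff(back$energy_eV) >= -1e-12))
  suppressWarnings(
    expect_error(export_spectrum(sp, file.path(tempfile(), "no",
                                               "x.tsv")),
                 "cannot write"))
})
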