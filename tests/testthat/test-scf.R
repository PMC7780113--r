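# SCF engine: convergence, invariances, embedding, population analysis.

test_that("H2 converges with a bound occupied orbital and symmetric
          charges", {
  h2 <- fragment_geometry(data.frame(element = "H",
                                     name = c("H1", "H2"),
                                     x = c(0, 0.74), y = 0, z = 0))
  scf <- scf_solve(h2, fx_params())
  expect_true(scf$converged)
  expect_lt(scf$orbital_energies[1], 0)
  expect_equal(scf$atomic_net_charges, c(0, 0), tolerance = 1e-10)
})

test_that("density matrix is idempotent with correct electron count", {
  scf <- scf_solve(make_toy_molecule("water"), fx_params())
  P <- scf$density
  expect_equal(sum(diag(P)), 8, tolerance = 1e-8)
  # P/2 is a projector in the orthonormal ZDO basis
  expect_lt(max(abs(P %*% P / 2 - P)), 1e-5)
  expect_equal(max(abs(P - t(P))), 0, tolerance = 1e-12)
  # orbital energies non-decreasing
  expect_true(all(diff(scf$orbital_energies) >= -1e-10))
})

test_that("atomic charges conserve total charge and show the water sign
          pattern", {
  w <- scf_solve(make_toy_molecule("water"), fx_params())
  q <- w$atomic_net_charges
  expect_lt(q[1], 0)
  expect_gt(q[2], 0)
  expect_gt(q[3], 0)
  expect_equal(sum(q), 0, tolerance = 1e-8)
  # charged fragment conserves its net charge
  s <- make_pcb_surrogate(protonated = TRUE)
  scf <- scf_solve(s$fragment, fx_params())
  expect_equal(sum(scf$atomic_net_charges), 1, tolerance = 1e-8)
  # refusal on unconverged input
  fake <- scf
  fake$converged <- FALSE
  expect_error(atomic_charges(fake), "unconverged")
})

test_that("total energy is invariant under rigid rotation + translation
          of fragment and charges", {
  frag <- make_toy_molecule("formaldehyde")
  env <- data.frame(x = c(3, -2.5), y = c(1, 0.5), z = c(0.5, -1),
                    q = c(0.3, -0.2))
  e1 <- scf_solve(frag, fx_params(), environment = env)
  Q <- rotation_about(c(0.3, 1, -0.5), 1.13)
  shift <- c(1.5, -0.7, 2.2)
  rot <- frag
  xyz <- frag_coords(frag) %*% t(Q)
  rot$atoms$x <- xyz[, 1] + shift[1]
  rot$atoms$y <- xyz[, 2] + shift[2]
  rot$atoms$z <- xyz[, 3] + shift[3]
  exyz <- as.matrix(env[, 1:3]) %*% t(Q)
  env2 <- data.frame(x = exyz[, 1] + shift[1], y = exyz[, 2] + shift[2],
                     z = exyz[, 3] + shift[3], q = env$q)
  e2 <- scf_solve(rot, fx_params(), environment = env2)
  expect_equal(e1$total_energy_eV, e2$total_energy_eV,
               tolerance = 1e-8 * 27.2 / abs(e1$total_energy_eV))
  expect_equal(e1$orbital_energies, e2$orbital_energies,
               tolerance = 1e-7)
})

test_that("external charges enter as the closed-form diagonal shift,
          linearly", {
  h <- fragment_geometry(data.frame(element = "C", name = "C1",
                                    x = 0, y = 0, z = 0))
  p <- fx_params()
  d <- 4.0; q <- 0.7
  ev_per_au <- phycospec:::EV_ANGSTROM_COULOMB
  vac <- build_core_hamiltonian(h, p)
  one <- build_core_hamiltonian(h, p,
                                data.frame(x = d, y = 0, z = 0, q = q))
  shift <- diag(one$hcore) - diag(vac$hcore)
  expect_equal(shift, rep(-q / d * ev_per_au, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # doubling the charge doubles the shift exactly
  two <- build_core_hamiltonian(h, p,
                                data.frame(x = d, y = 0, z = 0,
                                           q = 2 * q))
  expect_equal(diag(two$hcore) - diag(vac$hcore), 2 * shift,
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero-magnitude charges leave the matrices untouched
  zero <- build_core_hamiltonian(h, p,
                                 data.frame(x = c(2, 3), y = 0, z = 1,
                                            q = c(0, 0)))
  expect_identical(zero$hcore, vac$hcore)
  # matrices are symmetric by construction
  w <- build_core_hamiltonian(make_toy_molecule("water"), p)
  expect_lt(max(abs(w$hcore - t(w$hcore))), 1e-12)
  expect_lt(max(abs(w$overlap - t(w$overlap))), 1e-12)
  # unparameterized element named in the error
  expect_error(fragment_geometry(data.frame(element = "P", name = "P1",
                                            x = 0, y = 0, z = 0)), "P")
  p_noS <- p
  p_noS$elements$S <- NULL
  sfrag <- fragment_geometry(data.frame(element = c("S", "H", "H"),
                                        name = c("S", "H1", "H2"),
                                        x = c(0, 1.34, -0.4),
                                        y = c(0, 0, 1.28), z = 0))
  expect_error(scf_solve(sfrag, p_noS), "S")
})

test_that("SCF energy decreases monotonically under pure damping", {
  for (frag in list(make_toy_molecule("water"),
                    make_toy_molecule("ethylene"))) {
    scf <- scf_solve(frag, indo_params(scf = list(diis = FALSE,
                                                  damping = 0.5)))
    expect_true(all(diff(scf$trajectory$energy_eV) < 1e-6))
  }
})

test_that("ethylene HOMO and LUMO are the pi and pi* orbitals", {
  scf <- scf_solve(make_toy_molecule("ethylene"), fx_params())
  bs <- scf$basis
  # out-of-plane p functions on the carbons (molecule lies in a plane)
  xyz <- frag_coords(scf$fragment)
  nrm <- phycospec:::unitv(phycospec:::crossv(xyz[2, ] - xyz[1, ],
                                              xyz[3, ] - xyz[1, ]))
  for (mo in c(scf$n_occupied, scf$n_occupied + 1)) {
    cvec <- scf$mo_coefficients[, mo]
    w_pi <- 0
    for (A in 1:2) {
      idx <- bs$first[A] + 1:3  # px, py, pz of carbon A
      pvec <- cvec[idx]
      w_pi <- w_pi + sum(pvec * nrm)^2
    }
    expect_gt(w_pi / sum(cvec^2), 0.95)
  }
})

test_that("odd electron counts are refused", {
  frag <- make_toy_molecule("water")
  frag$total_charge <- 1L
  expect_error(scf_solve(frag, fx_params()), "odd electron")
})
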