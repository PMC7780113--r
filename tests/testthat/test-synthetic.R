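# Synthetic generators: geometry sanity, determinism, round trips.

test_that("toy molecules have the advertised geometry", {
  et <- make_toy_molecule("ethylene")
  expect_equal(n_atoms(et), 6)
  # planar, with the C=C bond along x
  expect_equal(et$atoms$x[2] - et$atoms$x[1], 1.337, tolerance = 1e-9)
  spans <- apply(frag_coords(et), 2, function(v) diff(range(v)))
  expect_equal(min(spans), 0, tolerance = 1e-9)
  w <- make_toy_molecule("water")
  d <- phycospec:::pairwise_dist(frag_coords(w), frag_coords(w))
  expect_equal(d[1, 2], 0.9572, tolerance = 1e-10)
  expect_equal(d[1, 3], 0.9572, tolerance = 1e-10)
  ang <- acos(sum((frag_coords(w)[2, ] - frag_coords(w)[1, ]) *
                    (frag_coords(w)[3, ] - frag_coords(w)[1, ])) /
                0.9572^2) * 180 / pi
  expect_equal(ang, 104.52, tolerance = 1e-6)
  expect_error(make_toy_molecule("benzene"))
  # every toy passes valence completion unchanged and converges
  for (nm in c("ethylene", "s_trans_butadiene", "hexatriene",
               "formaldehyde", "water", "pyrrole")) {
    frag <- make_toy_molecule(nm)
    expect_equal(n_atoms(place_hydrogens(frag)), n_atoms(frag))
    expect_true(scf_solve(frag, fx_params())$converged)
  }
})

test_that("surrogate protonation toggles one atom and one unit of
          charge", {
  sp <- make_pcb_surrogate(protonated = TRUE)
  sn <- make_pcb_surrogate(protonated = FALSE)
  expect_equal(n_atoms(sp$fragment), n_atoms(sn$fragment) + 1)
  expect_equal(sp$fragment$total_charge, sn$fragment$total_charge + 1L)
  expect_equal(sp$spec$ring_nitrogens$B, "NB")
  # longer bridge grows the conjugated system
  s3 <- make_pcb_surrogate(n_conjugated = 3)
  expect_gt(n_atoms(s3$fragment), n_atoms(sp$fragment))
  expect_error(make_pcb_surrogate(n_conjugated = 1))
  # planar by construction
  expect_true(all(abs(sp$fragment$atoms$z) < 1e-8))
  expect_true(scf_solve(sp$fragment, fx_params())$converged)
})

test_that("water shells respect the packing constraints and the seed", {
  solute <- fx_surrogate()$fragment
  w1 <- make_water_shell(solute, 15, r_min = 2.5, r_max = 5.5, seed = 9)
  w2 <- make_water_shell(solute, 15, r_min = 2.5, r_max = 5.5, seed = 9)
  expect_identical(w1, w2)
  w3 <- make_water_shell(solute, 15, r_min = 2.5, r_max = 5.5, seed = 10)
  expect_false(identical(w1, w3))
  o <- as.matrix(w1[w1$element == "O", c("x", "y", "z")])
  expect_equal(nrow(o), 15)
  doo <- phycospec:::pairwise_dist(o, o)
  expect_true(all(doo[upper.tri(doo)] >= 2.6))
  dmin <- apply(phycospec:::pairwise_dist(o, frag_coords(solute)), 1,
                min)
  expect_true(all(dmin >= 2.5 & dmin <= 5.5))
  # O-H geometry is rigid
  for (i in unique(w1$water)[1:3]) {
    m <- as.matrix(w1[w1$water == i, c("x", "y", "z")])
    expect_equal(phycospec:::vnorm(m[2, ] - m[1, ]), 0.9572,
                 tolerance = 1e-10)
    expect_equal(phycospec:::vnorm(m[3, ] - m[1, ]), 0.9572,
                 tolerance = 1e-10)
  }
  expect_equal(nrow(make_water_shell(solute, 0, seed = 1)), 0)
  # impossible packing reports the count placed
  expect_error(make_water_shell(make_toy_molecule("water"), 500,
                                r_min = 2.5, r_max = 2.9, seed = 1),
               "placed")
})

test_that("charge shells reproduce the shell-theorem potential", {
  sh1 <- make_charge_shell(c(0, 0, 0), 5, 1, -1)
  expect_equal(nrow(sh1), 1)
  expect_equal(phycospec:::vnorm(as.numeric(sh1[1, c("x", "y", "z")])),
               5, tolerance = 1e-12)
  shn <- make_charge_shell(c(1, 2, 3), 10, 500, 3)
  expect_equal(sum(shn$q), 3, tolerance = 1e-12)
  pot <- sum(shn$q / sqrt((shn$x - 1)^2 + (shn$y - 2)^2 +
                            (shn$z - 3)^2))
  expect_equal(pot, 3 / 10, tolerance = 1e-3)
  sh0 <- make_charge_shell(c(0, 0, 0), 8, 64, 0)
  expect_identical(sum(sh0$q), 0)
})

test_that("mini-PDB files round-trip through read_pdb", {
  s <- make_pcb_surrogate()
  w <- make_water_shell(s$fragment, 3, seed = 4)
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(list(s$fragment), waters = w, path = f)
  st <- read_pdb(f)
  expect_equal(nrow(st$atoms), n_atoms(s$fragment) + 9)
  expect_setequal(unique(st$atoms$chain), c("X", "W"))
  expect_equal(sum(st$atoms$kind == "water"), 9)
  # coordinates to 3 decimals
  orig <- frag_coords(s$fragment)
  got <- as.matrix(st$atoms[st$atoms$chain == "X", c("x", "y", "z")])
  expect_equal(unname(got), unname(round(orig, 3)), tolerance = 1e-9)
  # byte-identical rewrite (seeded generators, fixed inputs)
  f2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(list(s$fragment), waters = w, path = f2)
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))
})

test_that("synthetic peptides build valid windows for all supported
          residues", {
  pep <- make_peptide_chain("GASCK")
  expect_s3_class(pep, "pdb_structure")
  w <- build_tripeptide_windows(pep, "A")
  expect_length(w, 5)
  for (wi in w) {
    expect_equal(phycospec:::n_electrons(wi$fragment) %% 2, 0)
  }
  expect_error(make_peptide_chain("GXZ"), "unsupported")
})
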