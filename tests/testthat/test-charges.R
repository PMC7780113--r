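# Environment charge model: residue charges, water charges, radius
# selection, counter ions.

test_that("window SCF charges conserve the fragment charge", {
  pep <- make_peptide_chain("GGG")
  w <- build_tripeptide_windows(pep, "A")
  p <- fx_params()
  for (wi in w) {
    q <- scf_solve(wi$fragment, p)$atomic_net_charges
    expect_equal(sum(q), wi$fragment$total_charge, tolerance = 1e-6)
  }
  # deprotonated Asp window carries and conserves -1
  pd <- make_peptide_chain("GDG")
  wd <- build_tripeptide_windows(pd, "A")
  expect_equal(wd[[2]]$fragment$total_charge, -1L)
  qd <- scf_solve(wd[[2]]$fragment, p)$atomic_net_charges
  expect_equal(sum(qd), -1, tolerance = 1e-6)
})

test_that("mirror-equivalent glycine hydrogens get equal charges", {
  # the extended backbone is planar, so the two HA on each CA are mirror
  # images through the backbone plane
  pep <- make_peptide_chain("GGG")
  w <- build_tripeptide_windows(pep, "A")
  frag <- w[[2]]$fragment
  q <- scf_solve(frag, fx_params())$atomic_net_charges
  ca_idx <- which(frag$atoms$name == "CA")
  nb <- phycospec:::neighbor_list(frag)
  for (ca in ca_idx) {
    h <- nb[[ca]][frag$atoms$element[nb[[ca]]] == "H"]
    if (length(h) == 2) {
      expect_equal(q[h[1]], q[h[2]], tolerance = 1e-4)
    }
  }
})

test_that("derive_residue_charges covers each residue exactly once", {
  pep <- make_peptide_chain("GGAGG")
  w <- build_tripeptide_windows(pep, "A")
  tab <- derive_residue_charges(w, fx_params(), engine = "template")
  expect_setequal(unique(tab$resno), 1:5)
  heavy <- tab[tab$element != "H", ]
  expect_false(any(duplicated(paste(heavy$resno, heavy$atom_name))))
  # template fast mode: residues sum to their formal charges
  expect_equal(as.numeric(tapply(tab$q, tab$resno, sum)), rep(0, 5),
               tolerance = 1e-10)
})

test_that("water charges use the fixed constants and near-neutrality", {
  const <- water_charge_constants()
  expect_equal(const$q_O, -0.3307)
  expect_equal(const$q_H, 0.1653)
  w <- make_water_shell(make_toy_molecule("ethylene"), 1, seed = 5)
  pc <- assign_water_charges(w)
  expect_equal(pc$q, c(-0.3307, 0.1653, 0.1653))
  expect_lt(abs(sum(pc$q)), 1e-4 + 1e-12)
  # zero waters give an empty list
  none <- assign_water_charges(make_water_shell(
    make_toy_molecule("ethylene"), 0, seed = 1))
  expect_equal(nrow(none), 0)
  # malformed triplet rejected
  bad <- w
  bad$element <- c("H", "O", "H")
  expect_error(assign_water_charges(bad), "triplet")
  expect_error(water_charge_constants(-0.5, 0.1), "neutral")
})

test_that("radius selection uses a closed interval on the minimum
          distance", {
  frag <- make_toy_molecule("ethylene")
  xyz <- frag_coords(frag)
  # the molecule is planar in z = 0; a charge 5.0 Angstrom above an atom
  # has that atom as its unique nearest neighbor at exactly 5.0
  src <- data.frame(x = xyz[1, 1], y = xyz[1, 2], z = xyz[1, 3] + 5,
                    q = 0.5)
  expect_equal(nrow(build_environment(src, frag, 5.0)$charges), 1)
  expect_equal(nrow(build_environment(src, frag, 4.99)$charges), 0)
  expect_equal(nrow(build_environment(src, frag, 0)$charges), 0)
})

test_that("environment selection is monotone, order-independent, and
          purely filtering", {
  s <- fx_surrogate()
  set.seed(11)
  n <- 80
  src <- data.frame(x = runif(n, -9, 9), y = runif(n, -9, 9),
                    z = runif(n, -9, 9), q = runif(n, -0.5, 0.5),
                    chain = sample(c("A", "K"), n, TRUE),
                    resno = sample(1:9, n, TRUE),
                    atom_name = paste0("X", 1:n))
  radii <- c(2, 4, 6, 8)
  envs <- lapply(radii, function(R)
    build_environment(src, s$fragment, R))
  ns <- vapply(envs, function(e) nrow(e$charges), 0)
  expect_true(all(diff(ns) >= 0))
  for (k in 2:length(envs)) {
    expect_true(all(envs[[k - 1]]$charges$origin %in%
                      envs[[k]]$charges$origin))
  }
  # permuting the source order yields the same set
  perm <- src[sample(n), ]
  e1 <- build_environment(src, s$fragment, 6)
  e2 <- build_environment(perm, s$fragment, 6)
  expect_setequal(e1$charges$origin, e2$charges$origin)
  # chain exclusion removes exactly that chain, charges untouched
  ex <- build_environment(src, s$fragment, 6, exclusions = list("K"))
  expect_false(any(ex$charges$chain == "K"))
  kept <- e1$charges[e1$charges$chain != "K", ]
  expect_equal(sort(kept$q), sort(ex$charges$q))
})

test_that("counter ions neutralize to the nearest integer,
          deterministically", {
  s <- fx_surrogate()
  src <- data.frame(x = c(4, 5, -4), y = c(1, -2, 3), z = c(4, 5, -4),
                    q = c(1.2, 1.0, 0.8))
  env <- build_environment(src, s$fragment, 10)
  out <- neutralize_with_counter_ions(env, placement_seed = 42)
  ions <- out$charges[out$charges$source == "counter_ion", ]
  expect_equal(nrow(ions), 3)
  expect_true(all(ions$q == -1))
  expect_equal(round(sum(out$charges$q)), 0)
  # ions on the 12-15 Angstrom shell around the chromophore centroid
  ctr <- env$chromophore_centroid
  d <- sqrt((ions$x - ctr[1])^2 + (ions$y - ctr[2])^2 +
              (ions$z - ctr[3])^2)
  expect_true(all(d >= 12 & d <= 15))
  # same seed reproduces positions; neutral input is unchanged
  out2 <- neutralize_with_counter_ions(env, placement_seed = 42)
  expect_identical(out$charges, out2$charges)
  neutral <- build_environment(data.frame(x = 5, y = 0, z = 3, q = 0.2),
                               s$fragment, 10)
  expect_identical(neutralize_with_counter_ions(neutral, 1), neutral)
})

test_that("charge tables and environments round-trip through TSV", {
  pep <- make_peptide_chain("GGG")
  tab <- derive_residue_charges(build_tripeptide_windows(pep, "A"),
                                fx_params(), engine = "template")
  f <- tempfile(fileext = ".tsv")
  write_charge_table(tab, f)
  back <- read_charge_table(f)
  expect_equal(back$q, tab$q, tolerance = 1e-12)
  expect_equal(back$atom_name, tab$atom_name)
})
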