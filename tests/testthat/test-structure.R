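# PDB access, chromophore extraction and chemical completion.

test_that("read_pdb parses fixtures and honors the altLoc policy", {
  w <- make_toy_molecule("water")
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(list(w), path = f)
  st <- read_pdb(f)
  expect_s3_class(st, "pdb_structure")
  expect_equal(nrow(st$atoms), 3)
  expect_equal(length(unique(st$atoms$chain)), 1)
  # altLoc 'B' records are dropped with a warning
  lines <- readLines(f)
  atom_line <- grep("^HETATM", lines)[1]
  l <- lines[atom_line]
  substr(l, 17, 17) <- "B"
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(lines[seq_len(atom_line)], l,
               lines[-seq_len(atom_line)]), f2)
  w2 <- testthat::capture_warnings(st2 <- read_pdb(f2))
  expect_true(any(grepl("alternate location", w2)))
  expect_equal(nrow(st2$atoms), 3)
  # malformed coordinate record reports the line number
  bad <- lines
  bad[atom_line] <- paste0(substr(bad[atom_line], 1, 35), "xxxxxxxx",
                           substring(bad[atom_line], 44))
  f3 <- tempfile(fileext = ".pdb")
  writeLines(bad, f3)
  expect_error(read_pdb(f3), as.character(atom_line))
  expect_error(read_pdb(tempfile()), "not found")
  f4 <- tempfile(); writeLines(c("HEADER", "END"), f4)
  expect_error(read_pdb(f4), "empty structure")
})

test_that("extract_chromophore returns the hetero residue and caps the
          thioether", {
  s <- make_pcb_surrogate(protonated = FALSE)
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(list(s$fragment), path = f)
  st <- read_pdb(f)
  fr <- extract_chromophore(st, s$spec)
  expect_equal(n_atoms(fr), sum(s$fragment$atoms$element != "H"))
  # missing residue -> lookup error
  bad <- chromophore_spec("missing", chain_id = "X",
                          residue_number = 999)
  expect_error(extract_chromophore(st, bad), "lookup")
  # pyrrole ring connectivity is verified
  st2 <- st
  keep <- !(st2$atoms$name %in% c("C4C", "C5C"))
  st2$atoms <- st2$atoms[keep, , drop = FALSE]
  expect_error(extract_chromophore(st2, s$spec), "geometry error")
})

test_that("extraction is rotation covariant", {
  s <- make_pcb_surrogate(protonated = FALSE)
  f1 <- tempfile(fileext = ".pdb")
  write_mini_pdb(list(s$fragment), path = f1)
  fr1 <- extract_chromophore(read_pdb(f1), s$spec)
  Q <- rotation_about(c(1, -1, 2), 0.62)
  rot <- s$fragment
  xyz <- frag_coords(rot) %*% t(Q)
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  f2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(list(rot), path = f2)
  fr2 <- extract_chromophore(read_pdb(f2), s$spec)
  # PDB format keeps 3 decimals, so covariance holds to ~2e-3 Angstrom
  expect_equal(frag_coords(fr1) %*% t(Q), frag_coords(fr2),
               tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("place_hydrogens saturates to standard valence and is
          idempotent", {
  ch4 <- fragment_geometry(
    data.frame(element = "C", name = "C1", x = 0, y = 0, z = 0),
    bonds = data.frame(i = integer(), j = integer(), order = integer()))
  out <- place_hydrogens(ch4)
  expect_equal(n_atoms(out), 5)
  d <- phycospec:::pairwise_dist(frag_coords(out), frag_coords(out))
  expect_equal(unname(d[1, 2:5]), rep(1.09, 4), tolerance = 1e-10)
  # all H-C-H angles tetrahedral
  u <- sweep(frag_coords(out)[2:5, ], 2, frag_coords(out)[1, ])
  u <- u / 1.09
  cosang <- tcrossprod(u)[upper.tri(diag(4))]
  expect_equal(cosang, rep(-1 / 3, 6), tolerance = 1e-8)
  # planar sp2 nitrogen gets its H in the ring plane on the bisector
  py <- make_toy_molecule("pyrrole")
  expect_true(all(abs(py$atoms$z) < 1e-8))
  nH <- py$atoms[py$atoms$element == "H" & grepl("N", py$atoms$name), ]
  expect_equal(nrow(nH), 1)
  # idempotency, coordinate-exact
  again <- place_hydrogens(py)
  expect_identical(py$atoms, again$atoms)
  # impossible valence errors
  bad <- fragment_geometry(
    data.frame(element = c("O", "C", "C", "C"),
               name = c("O", "C1", "C2", "C3"),
               x = c(0, 1.4, -1.4, 0), y = c(0, 0, 0, 1.4), z = 0),
    bonds = data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = 2L))
  expect_error(place_hydrogens(bad), "valence")
})

test_that("protonate_chromophore adds one H per bare central nitrogen and
          is idempotent", {
  s <- make_pcb_surrogate(protonated = FALSE)
  frag <- s$fragment
  out <- protonate_chromophore(frag, s$spec)
  expect_equal(n_atoms(out), n_atoms(frag) + 1)
  expect_equal(out$total_charge, frag$total_charge + 1L)
  # already protonated input is unchanged
  again <- protonate_chromophore(out, s$spec)
  expect_identical(again$atoms, out$atoms)
  expect_equal(again$total_charge, out$total_charge)
  # missing named nitrogen -> spec error
  bad_spec <- chromophore_spec("x", ring_nitrogens = list(B = "NB",
                                                          C = "NOPE"))
  expect_error(protonate_chromophore(frag, bad_spec), "spec error")
})

test_that("tripeptide windows follow the capping rules", {
  pep <- make_peptide_chain("GGGGG")
  w <- build_tripeptide_windows(pep, "A")
  expect_length(w, 5)
  # terminal windows are built from two residues
  expect_equal(length(unique(w[[1]]$fragment$atoms$resno)), 2)
  expect_equal(length(unique(w[[5]]$fragment$atoms$resno)), 2)
  expect_equal(length(unique(w[[3]]$fragment$atoms$resno)), 3)
  # interior: N terminus bears exactly two hydrogens (-NH2), C side ends
  # in a methyl ketone (-COCH3)
  f3 <- w[[3]]$fragment
  expect_equal(w[[3]]$cap_style, "interior")
  nb <- phycospec:::neighbor_list(f3)
  n_idx <- which(f3$atoms$name == "N" &
                   f3$atoms$resno == min(f3$atoms$resno))
  expect_equal(sum(f3$atoms$element[nb[[n_idx]]] == "H"), 2)
  cm <- which(f3$atoms$name == "CM")
  expect_length(cm, 1)
  expect_equal(sum(f3$atoms$element[nb[[cm]]] == "H"), 3)
  # final window ends in -COOH
  f5 <- w[[5]]$fragment
  expect_equal(w[[5]]$cap_style, "c_terminal")
  oxt <- which(f5$atoms$name == "OXT")
  expect_length(oxt, 1)
  nb5 <- phycospec:::neighbor_list(f5)
  expect_equal(sum(f5$atoms$element[nb5[[oxt]]] == "H"), 1)
  # every window passes its own valence check: no deficit remains
  for (wi in w) {
    before <- n_atoms(wi$fragment)
    expect_equal(n_atoms(place_hydrogens(wi$fragment)), before)
  }
  # chain gaps skip the affected windows with a warning
  gap <- pep
  gap$atoms <- gap$atoms[gap$atoms$resno != 3, , drop = FALSE]
  wmsg <- testthat::capture_warnings(wg <- build_tripeptide_windows(gap,
                                                                    "A"))
  expect_true(any(grepl("gap", wmsg)))
  expect_lt(length(wg), 5)
})

test_that("fragments keep even electron counts for closed-shell use", {
  for (nm in c("ethylene", "water", "pyrrole", "formaldehyde")) {
    frag <- make_toy_molecule(nm)
    expect_equal(phycospec:::n_electrons(frag) %% 2, 0)
  }
  for (prot in c(TRUE, FALSE)) {
    frag <- make_pcb_surrogate(protonated = prot)$fragment
    expect_equal(phycospec:::n_electrons(frag) %% 2, 0)
  }
})
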