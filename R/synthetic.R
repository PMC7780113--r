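# Synthetic input generators: every structure needed to exercise the
# pipeline without external downloads.  All generators are pure functions
# of their arguments (and seed, where one applies).

# Run an expression with a private, seeded RNG stream, restoring the
# caller's stream afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Idealized toy molecules
#'
#' Builds small conjugated/polar molecules at idealized geometry from a
#' shipped bond-length/angle table; used as oracle systems for the SCF and
#' CI engines.  All are neutral closed-shell species.
#'
#' @param name one of `"ethylene"`, `"s_trans_butadiene"`,
#'   `"hexatriene"`, `"formaldehyde"`, `"water"`, `"pyrrole"`.
#' @return a `fragment_geometry` with explicit bond orders and hydrogens.
#' @examples
#' make_toy_molecule("ethylene")
#' @export
make_toy_molecule <- function(name = c("ethylene", "s_trans_butadiene",
                                       "hexatriene", "formaldehyde",
                                       "water", "pyrrole")) {
  name <- match.arg(name)
  if (name == "water") {
    ang <- 104.52 * pi / 180
    atoms <- data.frame(
      element = c("O", "H", "H"), name = c("O", "H1", "H2"),
      x = c(0, 0.9572 * sin(ang / 2), -0.9572 * sin(ang / 2)),
      y = c(0, 0.9572 * cos(ang / 2), 0.9572 * cos(ang / 2)),
      z = 0, stringsAsFactors = FALSE)
    return(fragment_geometry(atoms,
                             bonds = data.frame(i = c(1, 1), j = c(2, 3),
                                                order = 1L),
                             label = "water"))
  }
  if (name == "formaldehyde") {
    atoms <- data.frame(element = c("C", "O"), name = c("C1", "O1"),
                        x = c(0, 1.205), y = 0, z = 0,
                        stringsAsFactors = FALSE)
    frag <- fragment_geometry(atoms,
                              bonds = data.frame(i = 1, j = 2, order = 2L),
                              label = "formaldehyde")
    return(place_hydrogens(frag))
  }
  if (name == "pyrrole") {
    return(place_hydrogens(pyrrole_ring()))
  }
  # polyene chain: alternating double/single bonds, planar zigzag
  ncarb <- switch(name, ethylene = 2L, s_trans_butadiene = 4L,
                  hexatriene = 6L)
  pos <- polyene_backbone(ncarb)
  atoms <- data.frame(element = "C",
                      name = paste0("C", seq_len(ncarb)),
                      x = pos[, 1], y = pos[, 2], z = 0,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = seq_len(ncarb - 1), j = 2:ncarb,
                      order = rep_len(c(2L, 1L), ncarb - 1))
  frag <- fragment_geometry(atoms, bonds = bonds, label = name)
  place_hydrogens(frag)
}

# zigzag carbon backbone with alternating 1.337/1.454 Angstrom bonds
#' @keywords internal
polyene_backbone <- function(ncarb, lengths = c(1.337, 1.454),
                             sweep_deg = 30) {
  pos <- matrix(0, ncarb, 2)
  th <- sweep_deg * pi / 180
  for (k in 2:ncarb) {
    len <- lengths[1 + (k %% 2)]
    ang <- th * (-1)^k
    pos[k, ] <- pos[k - 1, ] + len * c(cos(ang), sin(ang))
  }
  # rotate so the first (double) bond lies along +x
  a <- atan2(pos[2, 2] - pos[1, 2], pos[2, 1] - pos[1, 1])
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  pos %*% rot
}

# planar pyrrole-type five-ring (regular pentagon, side 1.39 Angstrom)
#' @keywords internal
pyrrole_ring <- function() {
  rad <- 1.39 / (2 * sin(pi / 5))
  ang <- pi / 2 + 2 * pi * (0:4) / 5
  atoms <- data.frame(
    element = c("N", "C", "C", "C", "C"),
    name = c("N1", "C2", "C3", "C4", "C5"),
    x = rad * cos(ang), y = rad * sin(ang), z = 0,
    stringsAsFactors = FALSE)
  bonds <- data.frame(i = c(1, 2, 3, 4, 5), j = c(2, 3, 4, 5, 1),
                      order = c(1L, 2L, 1L, 2L, 1L))
  fragment_geometry(atoms, bonds = bonds, label = "pyrrole")
}

#' Methine-bridged bis-pyrrole surrogate for a bilin chromophore
#'
#' Builds a planar conjugated dipyrrin-like molecule: two pyrrole-type
#' rings joined by an odd methine bridge, with the two ring nitrogens
#' labeled `NB` and `NC` (rings B and C of the chromophore convention).
#' In the neutral form ring B carries the pyrrole N-H and ring C is an
#' imine; protonation adds the ring-C hydrogen and a +1 charge, mirroring
#' the protonated bilin treated by the pipeline.
#'
#' @param n_conjugated length control for the conjugated bridge
#'   (`>= 2`); `2` gives the single-methine dipyrrin, each increment adds
#'   a vinylene unit (`2*(n_conjugated-2)+1` bridge carbons).
#' @param protonated logical; protonate the ring C nitrogen?
#' @return list with elements `fragment` (a `fragment_geometry`) and
#'   `spec` (the matching [chromophore_spec()]).
#' @examples
#' s <- make_pcb_surrogate()
#' s$fragment$total_charge
#' @export
make_pcb_surrogate <- function(n_conjugated = 2, protonated = TRUE) {
  if (n_conjugated < 2) stop("n_conjugated must be >= 2")
  m <- 2L * (n_conjugated - 2L) + 1L  # bridge carbons, odd
  # bridge path from ring B attachment to ring C attachment
  npath <- m + 2L
  lens <- rep_len(c(1.44, 1.36), npath - 1)  # single, double, ...
  pos <- matrix(0, npath, 2)
  th <- 28 * pi / 180
  for (k in 2:npath) {
    ang <- th * (-1)^k
    pos[k, ] <- pos[k - 1, ] + lens[k - 1] * c(cos(ang), sin(ang))
  }
  ringB <- attach_ring(pos[1, ], pos[2, ], rot_sign = 1,
                       suffix = "B", imine = FALSE)
  ringC <- attach_ring(pos[npath, ], pos[npath - 1, ], rot_sign = -1,
                       suffix = "C", imine = TRUE)
  bridge <- if (m > 0) data.frame(
    element = "C", name = paste0("CM", seq_len(m)),
    x = pos[1 + seq_len(m), 1], y = pos[1 + seq_len(m), 2], z = 0,
    stringsAsFactors = FALSE) else NULL
  atoms <- rbind(ringB$atoms, ringC$atoms, bridge)
  nB <- nrow(ringB$atoms)
  nC <- nrow(ringC$atoms)
  bridge_idx <- nB + nC + seq_len(m)
  path_idx <- c(1L, bridge_idx, nB + 1L)  # C2B, CM*, C2C
  path_orders <- rep_len(c(1L, 2L), npath - 1)
  bonds <- rbind(
    ringB$bonds,
    within(ringC$bonds, { i <- i + nB; j <- j + nB }),
    data.frame(i = path_idx[-npath], j = path_idx[-1],
               order = path_orders))
  frag <- fragment_geometry(atoms, bonds = bonds,
                            label = sprintf("pcb_surrogate_n%d%s",
                                            n_conjugated,
                                            if (protonated) "_H+" else ""))
  frag <- place_hydrogens(frag)
  spec <- chromophore_spec("surrogate",
                           ring_nitrogens = list(B = "NB", C = "NC"))
  if (protonated) frag <- protonate_chromophore(frag, spec)
  list(fragment = frag, spec = spec)
}

# five-ring attached at `at` pointing away from `from`; vertex order
# alpha-C (attachment), N, alpha'-C, beta-C, beta-C
#' @keywords internal
attach_ring <- function(at, from, rot_sign, suffix, imine) {
  rad <- 1.39 / (2 * sin(pi / 5))
  dir <- unitv(c(at - from, 0))[1:2]
  center <- at + rad * dir
  v0 <- at - center
  rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                           sin(a) * v[1] + cos(a) * v[2])
  verts <- t(vapply(0:4, function(k) {
    center + rot2(v0, rot_sign * 2 * pi * k / 5)
  }, numeric(2)))
  if (imine) {
    # shorten the N=C bond to the imine value so that distance-based
    # bond perception recovers the double bond after a PDB round trip
    verts[2, ] <- verts[2, ] + 0.06 * unitv(c(verts[3, ] - verts[2, ],
                                              0))[1:2]
  }
  atoms <- data.frame(
    element = c("C", "N", "C", "C", "C"),
    name = paste0(c("C2", "N", "C5", "C4", "C3"), suffix),
    x = verts[, 1], y = verts[, 2], z = 0, stringsAsFactors = FALSE)
  orders <- if (imine) {
    # C2-N 1, N=C5 2, C5-C4 1, C4=C3 2, C3-C2 1 (+ exocyclic double)
    c(1L, 2L, 1L, 2L, 1L)
  } else {
    # C2-N 1, N-C5 1, C5=C4 2, C4-C3 1, C3=C2 2 (N-H pyrrole type)
    c(1L, 1L, 2L, 1L, 2L)
  }
  bonds <- data.frame(i = c(1, 2, 3, 4, 5), j = c(2, 3, 4, 5, 1),
                      order = orders)
  list(atoms = atoms, bonds = bonds)
}

#' Seeded pseudo-water shell around a solute
#'
#' Places rigid TIP3P-geometry waters (O-H 0.9572 Angstrom, H-O-H 104.52
#' degrees) by seeded rejection sampling: each oxygen lies between `r_min`
#' and `r_max` from the nearest solute atom, orientations are random, and
#' no two oxygens approach closer than 2.6 Angstrom.  This stands in for
#' solvent placement by molecular dynamics: it reproduces only the dense
#' polar point-charge shell, not real water structure.
#'
#' @param solute a `fragment_geometry`.
#' @param n_waters number of waters to place.
#' @param r_min,r_max shell bounds in Angstrom (`r_min >= 2.4`).
#' @param seed integer seed; the same seed reproduces coordinates exactly.
#' @return data frame with columns `water` (molecule index), `element`
#'   (`O`, `H`, `H` per molecule), `x`, `y`, `z`.
#' @examples
#' w <- make_water_shell(make_toy_molecule("ethylene"), 5, seed = 1)
#' @export
make_water_shell <- function(solute, n_waters, r_min = 2.5, r_max = 6,
                             seed = 1) {
  stopifnot(r_min >= 2.4, r_max > r_min)
  if (n_waters == 0) {
    return(data.frame(water = integer(), element = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  }
  xyz <- frag_coords(solute)
  with_seed(seed, {
    placed_o <- matrix(numeric(0), 0, 3)
    out <- vector("list", n_waters)
    placed <- 0L
    attempts <- 0L
    while (placed < n_waters && attempts < 1e5) {
      attempts <- attempts + 1L
      anchor <- xyz[sample.int(nrow(xyz), 1), ]
      dir <- stats::rnorm(3); dir <- dir / vnorm(dir)
      o <- anchor + stats::runif(1, r_min, r_max) * dir
      dmin <- min(sqrt(rowSums(sweep(xyz, 2, o)^2)))
      if (dmin < r_min || dmin > r_max) next
      if (nrow(placed_o) &&
            min(sqrt(rowSums(sweep(placed_o, 2, o)^2))) < 2.6) next
      u1 <- stats::rnorm(3); u1 <- u1 / vnorm(u1)
      p <- perpv(u1)
      phi <- stats::runif(1, 0, 2 * pi)
      p <- cos(phi) * p + sin(phi) * crossv(u1, p)
      ang <- 104.52 * pi / 180
      u2 <- cos(ang) * u1 + sin(ang) * p
      placed <- placed + 1L
      placed_o <- rbind(placed_o, o)
      out[[placed]] <- data.frame(
        water = placed, element = c("O", "H", "H"),
        x = c(o[1], o[1] + 0.9572 * u1[1], o[1] + 0.9572 * u2[1]),
        y = c(o[2], o[2] + 0.9572 * u1[2], o[2] + 0.9572 * u2[2]),
        z = c(o[3], o[3] + 0.9572 * u1[3], o[3] + 0.9572 * u2[3]))
    }
    if (placed < n_waters) {
      stop("could not place ", n_waters, " waters in 1e5 attempts (",
           placed, " placed)")
    }
    do.call(rbind, out)
  })
}

#' Synthetic spherical charge shell
#'
#' Distributes `n_charges` equal point charges on a sphere (Fibonacci
#' lattice) for analytic embedding tests: by the shell theorem the
#' potential inside a large-`n` shell approaches `total_q / radius`.
#'
#' @param center 3-vector, Angstrom.
#' @param radius sphere radius, Angstrom.
#' @param n_charges number of charges (`>= 1`).
#' @param total_q total charge, e.
#' @return point-charge data frame (`x`, `y`, `z`, `q`, `source`,
#'   `origin`).
#' @examples
#' sh <- make_charge_shell(c(0, 0, 0), 10, 100, -2)
#' sum(sh$q)
#' @export
make_charge_shell <- function(center, radius, n_charges, total_q) {
  stopifnot(n_charges >= 1)
  i <- seq_len(n_charges) - 0.5
  golden <- pi * (1 + sqrt(5))
  theta <- acos(1 - 2 * i / n_charges)
  phi <- golden * i
  data.frame(
    x = center[1] + radius * sin(theta) * cos(phi),
    y = center[2] + radius * sin(theta) * sin(phi),
    z = center[3] + radius * cos(theta),
    q = total_q / n_charges,
    source = "synthetic",
    origin = paste0("shell", seq_len(n_charges)),
    stringsAsFactors = FALSE)
}

#' Synthetic extended peptide chain
#'
#' Builds an idealized extended-conformation polypeptide as a synthetic
#' `pdb_structure` (heavy atoms only), for exercising the tripeptide
#' charge pipeline without a crystal structure.  Supported residues:
#' G, A, S, C, D, K (one-letter codes).
#'
#' @param sequence one-letter residue string, e.g. `"GGAGG"`.
#' @param chain_id chain identifier.
#' @param first_resno number of the first residue.
#' @return a `pdb_structure`.
#' @examples
#' make_peptide_chain("GGG")
#' @export
make_peptide_chain <- function(sequence = "GGGGG", chain_id = "A",
                               first_resno = 1L) {
  one2three <- c(G = "GLY", A = "ALA", S = "SER", C = "CYS", D = "ASP",
                 K = "LYS")
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(one2three))) {
    stop("unsupported residue(s): ",
         paste(setdiff(res, names(one2three)), collapse = ", "))
  }
  nres <- length(res)
  # extended backbone via sequential internal-coordinate placement
  deg <- pi / 180
  place <- function(a, b, c, len, ang, dih) {
    # position d with |cd| = len, angle bcd = ang, dihedral abcd = dih
    bc <- unitv(c - b); ab <- unitv(b - a)
    n <- unitv(crossv(ab, bc))
    m <- crossv(n, bc)
    d2 <- len * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  rows <- list()
  add <- function(el, nm, p, rn, rname) {
    rows[[length(rows) + 1]] <<- data.frame(
      element = el, name = nm, x = p[1], y = p[2], z = p[3],
      resname = rname, resno = rn, chain = chain_id, insert = "",
      kind = "polymer", stringsAsFactors = FALSE)
  }
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(pi - 111 * deg), sin(pi - 111 * deg), 0)
  for (i in seq_len(nres)) {
    rn <- first_resno + i - 1L
    rname <- one2three[[res[i]]]
    add("N", "N", N, rn, rname)
    add("C", "CA", CA, rn, rname)
    add("C", "C", C, rn, rname)
    # carbonyl oxygen: anti to the next amide nitrogen (psi = 180)
    O <- place(N, CA, C, 1.231, 121 * deg, 0)
    add("O", "O", O, rn, rname)
    side <- side_chain_atoms(res[i], N, CA, C)
    for (s in side) add(s$el, s$nm, s$p, rn, rname)
    if (i < nres) {
      Nn <- place(N, CA, C, 1.329, 116.6 * deg, pi)
      CAn <- place(CA, C, Nn, 1.458, 121.7 * deg, pi)
      Cn <- place(C, Nn, CAn, 1.525, 111 * deg, pi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  atoms <- do.call(rbind, rows)
  structure(list(atoms = atoms, source = "synthetic peptide"),
            class = "pdb_structure")
}

# crude idealized side chains (heavy atoms) branching from CA
#' @keywords internal
side_chain_atoms <- function(code, N, CA, C) {
  if (code == "G") return(list())
  tetra_dir <- function(a, b, center, side = 1) {
    u1 <- unitv(a - center); u2 <- unitv(b - center)
    bis <- -unitv(u1 + u2)
    nrm <- unitv(crossv(u1, u2))
    half <- 54.735 * pi / 180
    unitv(cos(half) * bis + side * sin(half) * nrm)
  }
  CB <- CA + 1.53 * tetra_dir(N, C, CA)
  out <- list(list(el = "C", nm = "CB", p = CB))
  if (code == "A") return(out)
  if (code == "S") {
    OG <- CB + 1.42 * tetra_dir(CA, CA + perpv(unitv(CB - CA)), CB)
    return(c(out, list(list(el = "O", nm = "OG", p = OG))))
  }
  if (code == "C") {
    SG <- CB + 1.81 * tetra_dir(CA, CA + perpv(unitv(CB - CA)), CB)
    return(c(out, list(list(el = "S", nm = "SG", p = SG))))
  }
  # zigzag extension helper: next atom continuing a chain a -> b
  ext <- function(a, b, len, side) {
    u <- unitv(b - a)
    p <- perpv(u)
    ang <- (180 - 112) * pi / 180
    b + len * unitv(cos(ang) * u + side * sin(ang) * p)
  }
  if (code == "D") {
    CG <- ext(CA, CB, 1.52, 1)
    u <- unitv(CG - CB); p <- perpv(u)
    OD1 <- CG + 1.25 * unitv(cos(120 * pi / 180) * (-u) +
                               sin(120 * pi / 180) * p)
    OD2 <- CG + 1.25 * unitv(cos(120 * pi / 180) * (-u) -
                               sin(120 * pi / 180) * p)
    return(c(out, list(list(el = "C", nm = "CG", p = CG),
                       list(el = "O", nm = "OD1", p = OD1),
                       list(el = "O", nm = "OD2", p = OD2))))
  }
  if (code == "K") {
    CG <- ext(CA, CB, 1.52, 1)
    CD <- ext(CB, CG, 1.52, -1)
    CE <- ext(CG, CD, 1.52, 1)
    NZ <- ext(CD, CE, 1.49, -1)
    return(c(out, list(list(el = "C", nm = "CG", p = CG),
                       list(el = "C", nm = "CD", p = CD),
                       list(el = "C", nm = "CE", p = CE),
                       list(el = "N", nm = "NZ", p = NZ))))
  }
  out
}

#' Write fragments and waters as a miniature PDB file
#'
#' Produces a fixed-column PDB readable by [read_pdb()]; coordinates are
#' preserved to the format's 3 decimals.
#'
#' @param fragments list of `fragment_geometry` objects (chain/residue
#'   metadata is taken from their atom tables), or a single fragment.
#' @param waters optional water data frame from [make_water_shell()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mini_pdb <- function(fragments, waters = NULL, path) {
  if (inherits(fragments, "fragment_geometry")) fragments <- list(fragments)
  tabs <- lapply(fragments, function(f) {
    a <- f$atoms
    data.frame(element = a$element, name = a$name, x = a$x, y = a$y,
               z = a$z, resname = a$resname, resno = a$resno,
               chain = a$chain, kind = a$kind %||% "hetero",
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, tabs)
  if (!is.null(waters) && nrow(waters)) {
    wt <- data.frame(element = waters$element,
                     name = ifelse(waters$element == "O", "O",
                                   paste0("H",
                                          ave(waters$element,
                                              waters$water,
                                              FUN = seq_along))),
                     x = waters$x, y = waters$y, z = waters$z,
                     resname = "HOH", resno = waters$water,
                     chain = "W", kind = "water",
                     stringsAsFactors = FALSE)
    at <- rbind(at, wt)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = ifelse(at$kind == "polymer", "ATOM", "HETATM"),
      resno = at$resno, resid = at$resname, chain = at$chain,
      eleno = seq_len(nrow(at)), elety = at$name,
      elesy = at$element, o = rep(1, nrow(at)), b = rep(0, nrow(at)))
    TRUE
  }, error = function(e) {
    stop("cannot write PDB to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
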