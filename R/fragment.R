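# Molecular fragments: the QM region container, bond perception, and
# rule-based chemical completion (hydrogens, protonation).

#' Construct a molecular fragment
#'
#' A `fragment_geometry` holds an ordered atom table, a bond list with
#' orders, and an integer total charge.  It is the quantum region passed to
#' the SCF engine and the unit the structure tools operate on.
#'
#' @param atoms data frame with at least columns `element`, `name`, `x`,
#'   `y`, `z`; optional `resname`, `resno`, `chain`, `kind`,
#'   `formal_charge` are filled with defaults.
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   `order`, or `NULL` to perceive bonds from distances.
#' @param total_charge integer net charge in units of e.
#' @param label free-text label.
#' @return an object of class `fragment_geometry`.
#' @examples
#' frag <- make_toy_molecule("water")
#' n_atoms(frag)
#' @export
fragment_geometry <- function(atoms, bonds = NULL, total_charge = 0L,
                              label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("element", "name", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(atoms$resname)) atoms$resname <- "LIG"
  if (is.null(atoms$resno)) atoms$resno <- 1L
  if (is.null(atoms$chain)) atoms$chain <- "X"
  if (is.null(atoms$kind)) atoms$kind <- "hetero"
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in fragment")
  }
  bad <- !element_supported(atoms$element)
  if (any(bad)) stop("unrecognized element symbol(s): ",
                     paste(unique(atoms$element[bad]), collapse = ", "))
  if (is.null(bonds)) {
    bonds <- perceive_bonds(atoms)
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$order)) bonds$order <- 1L
  }
  frag <- structure(list(atoms = atoms, bonds = bonds,
                         total_charge = as.integer(total_charge),
                         label = label),
                    class = "fragment_geometry")
  check_fragment(frag)
  frag
}

#' @export
print.fragment_geometry <- function(x, ...) {
  cat("<fragment_geometry> ", x$label, "\n", sep = "")
  comp <- table(x$atoms$element)
  cat("  atoms: ", nrow(x$atoms), " (",
      paste0(names(comp), comp, collapse = " "), ")\n", sep = "")
  cat("  bonds: ", nrow(x$bonds), "   total charge: ",
      x$total_charge, " e\n", sep = "")
  invisible(x)
}

#' Number of atoms in a fragment
#' @param fragment a `fragment_geometry`.
#' @return integer count.
#' @export
n_atoms <- function(fragment) nrow(fragment$atoms)

#' @keywords internal
frag_coords <- function(fragment) {
  as.matrix(fragment$atoms[, c("x", "y", "z")])
}

#' @keywords internal
n_electrons <- function(fragment) {
  sum(.valence_electrons[fragment$atoms$element]) - fragment$total_charge
}

# Structural sanity checks: valid bond indices, bonded pairs below 2.2 A.
#' @keywords internal
check_fragment <- function(frag) {
  b <- frag$bonds
  n <- nrow(frag$atoms)
  if (nrow(b)) {
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n | b$i == b$j)) {
      stop("bond list refers to invalid atom indices")
    }
    xyz <- frag_coords(frag)
    d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] -
                         xyz[b$j, , drop = FALSE])^2))
    if (any(d >= 2.2)) {
      stop("bonded pair separated by >= 2.2 Angstrom (max ",
           format(max(d), digits = 4), ")")
    }
  }
  invisible(frag)
}

# Target valence of a heavy atom given its formal charge (N+ -> 4, O- -> 1).
#' @keywords internal
target_valence <- function(element, formal_charge = 0L) {
  .standard_valence[element] + ifelse(element %in% c("N", "O"),
                                      formal_charge, 0L)
}

#' Perceive bonds from interatomic distances
#'
#' Single bonds are assigned where the distance is below 1.25x the sum of
#' covalent radii; double bonds are then assigned greedily (shortest first)
#' among pairs below element-specific double-bond thresholds, subject to
#' each atom's remaining valence and at most one double bond per atom.
#'
#' @param atoms atom table (see [fragment_geometry()]).
#' @return bond data frame with columns `i`, `j`, `order`.
#' @export
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(), j = integer(),
                               order = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- pairwise_dist(xyz, xyz)
  rc <- .covalent_radius[atoms$element]
  cut <- 1.25 * outer(rc, rc, "+")
  pairs <- which(upper.tri(d) & d < cut & d > 0.4, arr.ind = TRUE)
  if (!nrow(pairs)) {
    return(data.frame(i = integer(), j = integer(), order = integer()))
  }
  bonds <- data.frame(i = pairs[, 1], j = pairs[, 2], order = 1L)
  # double-bond thresholds by element pair (Angstrom)
  dbl_cut <- function(e1, e2) {
    key <- paste(sort(c(e1, e2)), collapse = "-")
    switch(key, "C-C" = 1.43, "C-N" = 1.365, "C-O" = 1.30,
           "N-N" = 1.32, "N-O" = 1.25, "O-O" = 1.35, 0)
  }
  dist_b <- d[cbind(bonds$i, bonds$j)]
  el <- atoms$element
  cand <- which(mapply(dbl_cut, el[bonds$i], el[bonds$j]) > dist_b)
  if (length(cand)) {
    cand <- cand[order(dist_b[cand])]
    val <- tapply(c(bonds$order, bonds$order), c(bonds$i, bonds$j), sum)
    cur <- numeric(n); cur[as.integer(names(val))] <- val
    has_dbl <- logical(n)
    tv <- target_valence(el, atoms$formal_charge %||% 0L)
    for (k in cand) {
      a <- bonds$i[k]; b <- bonds$j[k]
      if (!has_dbl[a] && !has_dbl[b] && cur[a] < tv[a] && cur[b] < tv[b]) {
        bonds$order[k] <- 2L
        cur[a] <- cur[a] + 1; cur[b] <- cur[b] + 1
        has_dbl[a] <- TRUE; has_dbl[b] <- TRUE
      }
    }
  }
  bonds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# New atom row derived from a parent atom's metadata (keeps whatever
# columns the table carries).
#' @keywords internal
derived_atom_row <- function(atoms, parent, element, name, pos) {
  row <- atoms[parent, , drop = FALSE]
  row$element <- element
  row$name <- name
  row$x <- pos[1]; row$y <- pos[2]; row$z <- pos[3]
  if (!is.null(row$formal_charge)) row$formal_charge <- 0L
  row
}

# Sum of bond orders at each atom.
#' @keywords internal
bond_order_sums <- function(frag) {
  n <- n_atoms(frag)
  out <- numeric(n)
  b <- frag$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      out[b$i[k]] <- out[b$i[k]] + b$order[k]
      out[b$j[k]] <- out[b$j[k]] + b$order[k]
    }
  }
  out
}

#' @keywords internal
neighbor_list <- function(frag) {
  n <- n_atoms(frag)
  nb <- vector("list", n)
  b <- frag$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], b$j[k])
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], b$i[k])
  }
  nb
}

#' Saturate a fragment with hydrogens at ideal geometry
#'
#' Every heavy atom is completed to its standard valence (adjusted by
#' formal charge) with hydrogens placed by ideal sp2/sp3 rules: atoms
#' carrying a double bond are treated as trigonal planar, others as
#' tetrahedral.  X-H distances are 1.09 (C), 1.01 (N), 0.96 (O) and 1.34
#' (S) Angstrom.  The construction is deterministic in the input order and
#' idempotent: a saturated fragment is returned unchanged.
#'
#' @param fragment a `fragment_geometry` with heavy atoms and bonds.
#' @return a `fragment_geometry` including the added hydrogens.
#' @examples
#' ch4 <- fragment_geometry(data.frame(element = "C", name = "C1",
#'                                     x = 0, y = 0, z = 0),
#'                          bonds = data.frame(i = integer(),
#'                                             j = integer(),
#'                                             order = integer()))
#' place_hydrogens(ch4)
#' @export
place_hydrogens <- function(fragment) {
  frag <- fragment
  orders <- bond_order_sums(frag)
  nb <- neighbor_list(frag)
  el <- frag$atoms$element
  tv <- target_valence(el, frag$atoms$formal_charge)
  xyz <- frag_coords(frag)
  heavy <- which(el != "H")
  if (any(orders[heavy] > tv[heavy])) {
    bad <- heavy[orders[heavy] > tv[heavy]][1]
    stop("atom ", frag$atoms$name[bad], " (", el[bad],
         ") exceeds its valence: chemistry error")
  }
  has_dbl <- logical(n_atoms(frag))
  b <- frag$bonds
  if (nrow(b)) {
    dbl <- b[b$order >= 2, , drop = FALSE]
    has_dbl[c(dbl$i, dbl$j)] <- TRUE
  }
  new_atoms <- list()
  new_bonds <- list()
  hcount <- 0L
  for (a in heavy) {
    deficit <- tv[a] - orders[a]
    if (deficit <= 0) next
    dirs <- hydrogen_directions(xyz[a, ],
                                xyz[nb[[a]], , drop = FALSE],
                                deficit, sp2 = has_dbl[a])
    dist <- .xh_length[el[a]]
    for (kk in seq_len(nrow(dirs))) {
      hcount <- hcount + 1L
      pos <- xyz[a, ] + dist * dirs[kk, ]
      new_atoms[[hcount]] <- derived_atom_row(
        frag$atoms, a, "H",
        paste0("H", frag$atoms$name[a], if (deficit > 1) kk else ""),
        pos)
      new_bonds[[hcount]] <- data.frame(i = a,
                                        j = n_atoms(frag) + hcount,
                                        order = 1L)
    }
  }
  if (hcount == 0L) return(frag)
  frag$atoms <- rbind(frag$atoms, do.call(rbind, new_atoms))
  frag$bonds <- rbind(frag$bonds, do.call(rbind, new_bonds))
  check_fragment(frag)
}

# Unit directions for `h` new substituents on an atom at `center` with
# existing neighbor coordinates `nbrs` (matrix, possibly 0 rows).
#' @keywords internal
hydrogen_directions <- function(center, nbrs, h, sp2 = FALSE) {
  k <- nrow(nbrs)
  tetra <- 109.471 * pi / 180
  if (k == 0) {
    # isolated atom: fixed tetrahedral reference frame
    base <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    return(base[seq_len(h), , drop = FALSE])
  }
  u <- sweep(nbrs, 2, center)
  u <- t(apply(u, 1, unitv))
  if (k == 1) {
    ax <- -u[1, ]
    p <- perpv(u[1, ])
    if (sp2 && h <= 2) {
      # trigonal: two directions at 120 degrees from the neighbor
      ang <- 120 * pi / 180
      d1 <- unitv(cos(ang) * u[1, ] + sin(ang) * p)
      d2 <- unitv(cos(ang) * u[1, ] - sin(ang) * p)
      return(rbind(d1, d2)[seq_len(h), , drop = FALSE])
    }
    # tetrahedral cone about -u
    phi <- (seq_len(h) - 1) * 2 * pi / max(h, 1)
    q <- crossv(u[1, ], p)
    off <- pi - tetra
    dirs <- t(vapply(phi, function(f) {
      unitv(cos(off) * ax + sin(off) * (cos(f) * p + sin(f) * q))
    }, numeric(3)))
    return(dirs)
  }
  if (k == 2) {
    bis <- -(u[1, ] + u[2, ])
    if (vnorm(bis) < 1e-8) bis <- perpv(u[1, ])
    bis <- unitv(bis)
    if (h == 1) return(matrix(bis, 1))
    nrm <- crossv(u[1, ], u[2, ])
    if (vnorm(nrm) < 1e-8) nrm <- perpv(u[1, ])
    nrm <- unitv(nrm)
    half <- tetra / 2
    return(rbind(unitv(cos(half) * bis + sin(half) * nrm),
                 unitv(cos(half) * bis - sin(half) * nrm))[
                   seq_len(h), , drop = FALSE])
  }
  dir <- -(colSums(u))
  if (vnorm(dir) < 1e-8) dir <- perpv(u[1, ])
  matrix(unitv(dir), 1)
}

#' Impose the protonated bilin form
#'
#' Ensures that the nitrogen atoms of the two central pyrrole rings (B and
#' C in the chromophore specification) each carry exactly one hydrogen.
#' For every hydrogen actually added the total charge is incremented by
#' +1 e.  Applying the operation twice is a no-op.
#'
#' @param fragment a `fragment_geometry`.
#' @param spec a [chromophore_spec()] naming the ring nitrogens.
#' @return the protonated `fragment_geometry`.
#' @examples
#' s <- make_pcb_surrogate(protonated = FALSE)
#' pf <- protonate_chromophore(s$fragment, s$spec)
#' pf$total_charge
#' @export
protonate_chromophore <- function(fragment, spec) {
  frag <- fragment
  for (ring in c("B", "C")) {
    nname <- spec$ring_nitrogens[[ring]]
    if (is.null(nname)) stop("chromophore spec lacks ring ", ring,
                             " nitrogen")
    idx <- which(frag$atoms$name == nname & frag$atoms$element == "N")
    if (!length(idx)) {
      stop("ring ", ring, " nitrogen '", nname,
           "' not found in fragment: spec error")
    }
    idx <- idx[1]
    nb <- neighbor_list(frag)[[idx]]
    has_h <- any(frag$atoms$element[nb] == "H")
    if (!has_h) {
      xyz <- frag_coords(frag)
      heavy_nb <- nb[frag$atoms$element[nb] != "H"]
      dirs <- hydrogen_directions(xyz[idx, ],
                                  xyz[heavy_nb, , drop = FALSE], 1,
                                  sp2 = TRUE)
      pos <- xyz[idx, ] + .xh_length["N"] * dirs[1, ]
      frag$atoms <- rbind(frag$atoms,
                          derived_atom_row(frag$atoms, idx, "H",
                                           paste0("H", nname), pos))
      frag$bonds <- rbind(frag$bonds,
                          data.frame(i = idx, j = n_atoms(frag),
                                     order = 1L))
      frag$total_charge <- frag$total_charge + 1L
      # the protonated nitrogen is a formal cation center
      frag$atoms$formal_charge[idx] <- frag$atoms$formal_charge[idx] + 1L
    }
  }
  check_fragment(frag)
}

#' Write a fragment as an XYZ file
#'
#' @param fragment a `fragment_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(fragment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n_atoms(fragment)), con)
  writeLines(paste0(fragment$label, " charge=", fragment$total_charge), con)
  a <- fragment$atoms
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z),
             con)
  invisible(path)
}

#' Read an XYZ file as a fragment
#'
#' Bonds are perceived from distances; the total charge is recovered from a
#' `charge=` token in the comment line when present.
#'
#' @param path XYZ file path.
#' @return a `fragment_geometry`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  comment <- lines[2]
  toks <- strsplit(trimws(lines[2 + seq_len(n)]), "[[:space:]]+")
  atoms <- data.frame(
    element = vapply(toks, `[`, "", 1),
    name = paste0(vapply(toks, `[`, "", 1), seq_len(n)),
    x = as.numeric(vapply(toks, `[`, "", 2)),
    y = as.numeric(vapply(toks, `[`, "", 3)),
    z = as.numeric(vapply(toks, `[`, "", 4)),
    stringsAsFactors = FALSE)
  chg <- 0L
  m <- regmatches(comment, regexpr("charge=-?[0-9]+", comment))
  if (length(m) && nzchar(m)) chg <- as.integer(sub("charge=", "", m))
  fragment_geometry(atoms, total_charge = chg,
                    label = sub("[[:space:]]*charge=-?[0-9]+", "", comment))
}
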