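# PDB structure access and chromophore / tripeptide fragment extraction.

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records through `bio3d::read.pdb` after a light
#' line-level validation pass that reports the first malformed coordinate
#' record by line number.  Alternate locations other than blank or `'A'`
#' are dropped with a warning; insertion codes are retained.
#'
#' @param path PDB file path.
#' @return an object of class `pdb_structure`: a list with the atom table
#'   (`atoms`) and the source path.
#' @examples
#' s <- make_pcb_surrogate()
#' f <- tempfile(fileext = ".pdb")
#' write_mini_pdb(list(s$fragment), path = f)
#' str6 <- read_pdb(f)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path)
  for (ln in which(rec)) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54)))))) {
      stop("unparseable coordinate record at line ", ln, " of ", path)
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("PDB format error in ", path, ": ",
                         conditionMessage(e))
                  })
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", " ", "A")
  if (any(!keep)) {
    warning(sum(!keep), " atom(s) with alternate location other than",
            " blank/'A' dropped")
    a <- a[keep, , drop = FALSE]
  }
  if (!nrow(a)) stop("empty structure after alternate-location filtering")
  el <- a$elesy
  el[is.na(el) | !nzchar(trimws(el))] <- NA
  el <- ifelse(is.na(el), guess_element(a$elety), trimws(el))
  el <- paste0(toupper(substr(el, 1, 1)),
               tolower(substring(el, 2)))
  resname <- trimws(a$resid)
  kind <- ifelse(resname %in% c("HOH", "WAT", "DOD", "SOL"), "water",
                 ifelse(a$type == "HETATM", "hetero", "polymer"))
  atoms <- data.frame(
    element = el, name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z,
    resname = resname, resno = a$resno,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    kind = kind, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat("<pdb_structure> ", x$source, "\n", sep = "")
  cat("  atoms:", nrow(a), " chains:",
      paste(sort(unique(a$chain)), collapse = " "), "\n")
  cat("  polymer:", sum(a$kind == "polymer"),
      " hetero:", sum(a$kind == "hetero"),
      " water:", sum(a$kind == "water"), "\n")
  invisible(x)
}

#' Chromophore specification
#'
#' Identifies a bilin chromophore inside a structure: its hetero residue,
#' the atom names of the ring nitrogens (rings B and C are required; they
#' are the protonation sites of the central pyrrole rings), and the
#' cysteine residue of the thioether linkage.
#'
#' @param chromophore_id label such as `"alpha84"`, `"beta84"`,
#'   `"beta155"`, or free text.
#' @param chain_id chain of the hetero residue.
#' @param residue_number residue number of the hetero residue.
#' @param ring_nitrogens named list mapping ring labels (`A`-`D`) to atom
#'   names; `B` and `C` are mandatory.
#' @param linkage optional `list(chain =, resno =)` of the linking
#'   cysteine.
#' @return an object of class `chromophore_spec`.
#' @export
chromophore_spec <- function(chromophore_id, chain_id = "X",
                             residue_number = 1L,
                             ring_nitrogens = list(B = "NB", C = "NC"),
                             linkage = NULL) {
  if (is.null(ring_nitrogens$B) || is.null(ring_nitrogens$C)) {
    stop("ring_nitrogens must name at least rings B and C")
  }
  structure(list(chromophore_id = chromophore_id, chain_id = chain_id,
                 residue_number = as.integer(residue_number),
                 ring_nitrogens = ring_nitrogens, linkage = linkage),
            class = "chromophore_spec")
}

# TRUE if atom `n_idx` lies on a cycle of length <= maxlen.
#' @keywords internal
in_small_ring <- function(frag, n_idx, maxlen = 6) {
  nb <- neighbor_list(frag)
  nbs <- nb[[n_idx]]
  if (length(nbs) < 2) return(FALSE)
  # breadth-first search from one neighbor to another avoiding n_idx
  for (a in seq_along(nbs)) {
    for (b in seq_along(nbs)) {
      if (a >= b) next
      start <- nbs[a]; goal <- nbs[b]
      seen <- c(n_idx, start)
      frontier <- start
      depth <- 1
      while (length(frontier) && depth < maxlen - 1) {
        nxt <- unique(unlist(nb[frontier]))
        nxt <- setdiff(nxt, seen)
        if (goal %in% nxt) return(TRUE)
        seen <- c(seen, nxt)
        frontier <- nxt
        depth <- depth + 1
      }
    }
  }
  FALSE
}

#' Extract a chromophore QM region from a structure
#'
#' Pulls the heavy atoms of the hetero residue named in the specification,
#' perceives bonds, severs the thioether bond to the linking cysteine and
#' caps the dangling chromophore carbon with a hydrogen link atom placed
#' along the former bond direction at 1.09 Angstrom.
#'
#' @param structure a `pdb_structure` from [read_pdb()].
#' @param spec a [chromophore_spec()].
#' @return a `fragment_geometry` (neutral; protonation is applied
#'   separately by [protonate_chromophore()]).
#' @export
extract_chromophore <- function(structure, spec) {
  a <- structure$atoms
  sel <- a$chain == spec$chain_id & a$resno == spec$residue_number
  if (!any(sel)) {
    stop("chromophore residue ", spec$residue_number, " in chain ",
         spec$chain_id, " not found: lookup error")
  }
  atoms <- a[sel & a$element != "H", , drop = FALSE]
  atoms$formal_charge <- 0L
  frag <- fragment_geometry(atoms, total_charge = 0L,
                            label = spec$chromophore_id)
  # sever the cysteinyl thioether linkage and cap with a hydrogen
  if (!is.null(spec$linkage)) {
    cys <- a[a$chain == spec$linkage$chain &
               a$resno == spec$linkage$resno & a$element == "S", ,
             drop = FALSE]
    if (nrow(cys)) {
      xyz <- frag_coords(frag)
      d <- pairwise_dist(xyz, as.matrix(cys[, c("x", "y", "z")]))
      hit <- which(d < 2.2, arr.ind = TRUE)
      if (nrow(hit)) {
        ci <- hit[which.min(d[hit]), 1]
        sxyz <- as.numeric(cys[hit[which.min(d[hit]), 2],
                               c("x", "y", "z")])
        dir <- unitv(sxyz - xyz[ci, ])
        pos <- xyz[ci, ] + 1.09 * dir
        frag$atoms <- rbind(frag$atoms,
                            derived_atom_row(frag$atoms, ci, "H",
                                             "HLNK", pos))
        frag$bonds <- rbind(frag$bonds,
                            data.frame(i = ci, j = n_atoms(frag),
                                       order = 1L))
      }
    }
  }
  # every named pyrrole nitrogen must close a five-membered ring
  for (ring in names(spec$ring_nitrogens)) {
    nn <- spec$ring_nitrogens[[ring]]
    idx <- which(frag$atoms$name == nn)
    if (length(idx) && !in_small_ring(frag, idx[1], maxlen = 5)) {
      stop("pyrrole ring ", ring, " around atom ", nn,
           " is not closable: geometry error")
    }
  }
  check_fragment(frag)
}

# Default ionizable side-chain states at pH 7 (atom-level formal charges).
.residue_formal_charges <- list(
  ASP = c(OD2 = -1L), GLU = c(OE2 = -1L),
  LYS = c(NZ = 1L), ARG = c(NH2 = 1L))

#' Build capped tripeptide windows along a chain
#'
#' For each residue position i of a chain, the residues i-1, i, i+1 are cut
#' out as a fragment (terminal residues use their two available
#' neighbors).  The window's N terminus is left as an -NH2 amine; the C
#' side is capped as a methyl ketone (-COCH3) with the methyl carbon at the
#' position of the removed next residue's nitrogen, except at the chain's
#' C terminus where the native -COOH is completed.  Hydrogens are then
#' placed with [place_hydrogens()].
#'
#' @param structure a `pdb_structure`.
#' @param chain_id chain identifier.
#' @param formal_charges named list mapping residue names to named integer
#'   vectors of atom formal charges; defaults to standard ionization
#'   states at pH 7 (Asp/Glu deprotonated, Lys/Arg protonated).
#' @return a list of `tripeptide_window` objects, each with elements
#'   `center` (`list(chain, resno)`), `fragment` and `cap_style`
#'   (`"interior"` or `"c_terminal"`).
#' @export
build_tripeptide_windows <- function(structure, chain_id,
                                     formal_charges =
                                       .residue_formal_charges) {
  a <- structure$atoms
  pol <- a[a$chain == chain_id & a$kind == "polymer" & a$element != "H", ,
           drop = FALSE]
  resnos <- sort(unique(pol$resno))
  if (length(resnos) < 3) stop("chain ", chain_id, " has fewer than 3",
                               " residues")
  last_resno <- resnos[length(resnos)]
  windows <- list()
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    lo <- if (k > 1) resnos[k - 1] else r
    hi <- if (k < length(resnos)) resnos[k + 1] else r
    if ((k > 1 && lo != r - 1) || (k < length(resnos) && hi != r + 1)) {
      warning("chain gap around residue ", r, ": window skipped")
      next
    }
    take <- pol$resno %in% unique(c(lo, r, hi))
    atoms <- pol[take, , drop = FALSE]
    atoms$formal_charge <- 0L
    for (rn in unique(atoms$resname)) {
      fc <- formal_charges[[rn]]
      if (!is.null(fc)) {
        for (an in names(fc)) {
          hitrows <- atoms$name == an & atoms$resname == rn
          atoms$formal_charge[hitrows] <- fc[[an]]
        }
      }
    }
    cap_style <- if (max(c(lo, r, hi)) == last_resno) "c_terminal"
                 else "interior"
    # cap the C side
    ci <- which(atoms$resno == max(lo, r, hi) & atoms$name == "C")
    if (cap_style == "interior" && length(ci)) {
      nxt <- pol[pol$resno == max(lo, r, hi) + 1 & pol$name == "N", ,
                 drop = FALSE]
      if (nrow(nxt)) {
        cm <- atoms[ci, ]
        cm$element <- "C"; cm$name <- "CM"
        cm$x <- nxt$x[1]; cm$y <- nxt$y[1]; cm$z <- nxt$z[1]
        atoms <- rbind(atoms, cm)
      }
    } else if (cap_style == "c_terminal" && length(ci) &&
               !any(atoms$name == "OXT" &
                      atoms$resno == max(lo, r, hi))) {
      # complete the carboxyl group geometrically
      cat_ <- as.numeric(atoms[ci, c("x", "y", "z")])
      ca <- atoms[atoms$resno == max(lo, r, hi) & atoms$name == "CA", ]
      o <- atoms[atoms$resno == max(lo, r, hi) & atoms$name == "O", ]
      if (nrow(ca) && nrow(o)) {
        d <- -(unitv(as.numeric(ca[1, c("x", "y", "z")]) - cat_) +
                 unitv(as.numeric(o[1, c("x", "y", "z")]) - cat_))
        pos <- cat_ + 1.32 * unitv(d)
        ox <- atoms[ci, ]
        ox$element <- "O"; ox$name <- "OXT"
        ox$x <- pos[1]; ox$y <- pos[2]; ox$z <- pos[3]
        atoms <- rbind(atoms, ox)
      }
    }
    frag <- fragment_geometry(atoms,
                              total_charge = sum(atoms$formal_charge),
                              label = sprintf("window %s%d", chain_id, r))
    frag <- place_hydrogens(frag)
    windows[[length(windows) + 1]] <-
      structure(list(center = list(chain = chain_id, resno = r),
                     fragment = frag, cap_style = cap_style),
                class = "tripeptide_window")
  }
  windows
}
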