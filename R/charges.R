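# Point-charge description of the environment: residue charges from the
# sliding capped-tripeptide protocol, fixed water charges, counter ions,
# and radius-based selection around a chromophore.

#' Water charge constants
#'
#' Fixed point charges assigned to water atoms; the defaults are the
#' HF/STO-3G-derived values used throughout the pipeline (-0.3307 e on O,
#' +0.1653 e on each H), which are near-neutral per molecule.
#'
#' @param q_O,q_H charges in e.
#' @return list with `q_O` and `q_H`.
#' @export
water_charge_constants <- function(q_O = -0.3307, q_H = 0.1653) {
  if (abs(q_O + 2 * q_H) > 1e-4 + 1e-12) {
    stop("water charges are not neutral within 1e-4 e per molecule")
  }
  list(q_O = q_O, q_H = q_H)
}

#' Assign point charges to water molecules
#'
#' @param water_coords data frame from [make_water_shell()] (columns
#'   `water`, `element`, `x`, `y`, `z`; each molecule O then two H), or a
#'   list of 3x3 coordinate matrices with rows O, H, H.
#' @param constants a [water_charge_constants()] list.
#' @return point-charge data frame (`x`, `y`, `z`, `q`, `source`,
#'   `origin`).
#' @examples
#' w <- make_water_shell(make_toy_molecule("ethylene"), 3, seed = 1)
#' assign_water_charges(w)
#' @export
assign_water_charges <- function(water_coords,
                                 constants = water_charge_constants()) {
  if (is.list(water_coords) && !is.data.frame(water_coords)) {
    water_coords <- do.call(rbind, lapply(seq_along(water_coords),
      function(i) {
        m <- water_coords[[i]]
        if (!is.matrix(m) || nrow(m) != 3 || ncol(m) != 3) {
          stop("malformed water triplet at index ", i)
        }
        data.frame(water = i, element = c("O", "H", "H"),
                   x = m[, 1], y = m[, 2], z = m[, 3])
      }))
  }
  if (!nrow(water_coords)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      q = numeric(), source = character(),
                      origin = character(), stringsAsFactors = FALSE))
  }
  ok <- all(tapply(water_coords$element, water_coords$water,
                   function(e) length(e) == 3 &&
                     identical(as.character(e), c("O", "H", "H"))))
  if (!ok) stop("each water must be an O,H,H triplet (O first)")
  data.frame(
    x = water_coords$x, y = water_coords$y, z = water_coords$z,
    q = ifelse(water_coords$element == "O", constants$q_O,
               constants$q_H),
    source = "water",
    origin = paste0("water", water_coords$water),
    stringsAsFactors = FALSE)
}

#' Derive per-residue atomic charges from tripeptide windows
#'
#' For every window a ground-state SCF is run on the capped fragment and
#' ZDO net charges are computed; only the atoms of the central residue
#' (including its placed hydrogens) enter the returned table.  Windows
#' whose SCF fails fall back to the static per-residue template table with
#' a warning.  `engine = "template"` skips the SCF entirely (fast mode).
#'
#' @param windows list of windows from [build_tripeptide_windows()].
#' @param params an [indo_params()] set.
#' @param engine `"scf"` or `"template"`.
#' @param template template table (data frame `resname`, `atom_name`,
#'   `q`); default ships with the package.
#' @return charge table: data frame with columns `chain`, `resno`,
#'   `resname`, `atom_name`, `element`, `x`, `y`, `z`, `q`.
#' @export
derive_residue_charges <- function(windows, params = indo_params(),
                                   engine = c("scf", "template"),
                                   template = NULL) {
  engine <- match.arg(engine)
  if (is.null(template)) template <- residue_charge_template()
  out <- lapply(windows, function(w) {
    frag <- w$fragment
    central <- frag$atoms$resno == w$center$resno
    q <- NULL
    if (engine == "scf") {
      q <- tryCatch(scf_solve(frag, params)$atomic_net_charges,
                    error = function(e) {
                      warning("window ", w$center$chain, w$center$resno,
                              ": SCF failed (", conditionMessage(e),
                              "); template charges used")
                      NULL
                    })
    }
    if (is.null(q)) q <- template_charges(frag, template)
    data.frame(chain = w$center$chain,
               resno = frag$atoms$resno[central],
               resname = frag$atoms$resname[central],
               atom_name = frag$atoms$name[central],
               element = frag$atoms$element[central],
               x = frag$atoms$x[central], y = frag$atoms$y[central],
               z = frag$atoms$z[central],
               q = q[central], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @keywords internal
residue_charge_template <- function() {
  path <- system.file("extdata", "residue_charge_template.tsv",
                      package = "phycospec")
  if (!nzchar(path)) {
    path <- file.path("inst", "extdata", "residue_charge_template.tsv")
  }
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# Template charges for a whole fragment: table lookup by (resname,
# atom_name), element defaults otherwise, then a uniform shift per residue
# so each residue sums exactly to its formal charge.
#' @keywords internal
template_charges <- function(frag, template) {
  a <- frag$atoms
  q <- numeric(nrow(a))
  keyt <- paste(template$resname, template$atom_name)
  hit <- match(paste(a$resname, a$name), keyt)
  q[!is.na(hit)] <- template$q[hit[!is.na(hit)]]
  defaults <- c(H = 0.09, C = 0.0, N = -0.3, O = -0.4, S = -0.1)
  q[is.na(hit)] <- defaults[a$element[is.na(hit)]]
  for (rn in unique(a$resno)) {
    idx <- a$resno == rn
    target <- sum(a$formal_charge[idx])
    q[idx] <- q[idx] + (target - sum(q[idx])) / sum(idx)
  }
  q
}

#' Assemble the point-charge environment within a radius
#'
#' Selects candidate point charges whose minimum distance to any
#' chromophore atom is `<= R` (closed interval, atom-wise).  The
#' chromophore's own residue, the linking cysteine side-chain atoms beyond
#' the boundary cap (SG and its hydrogen), and any requested exclusions
#' (e.g. a whole chain for a chain-removal experiment) are removed before
#' selection.  Charges closer than 0.5 Angstrom to a chromophore atom are
#' dropped with a warning.
#'
#' @param sources point-charge data frame: columns `x`, `y`, `z`, `q`,
#'   optionally `source`, `origin`, `chain`, `resno`, `atom_name`.  Charge
#'   tables from [derive_residue_charges()] are accepted directly.
#' @param chromophore the chromophore `fragment_geometry`.
#' @param R inclusion radius in Angstrom (`>= 0`).
#' @param exclusions list of exclusions: chain ids (character) and/or
#'   `list(chain =, resno =)` residue selectors.
#' @param spec optional [chromophore_spec()]; used to exclude the
#'   chromophore's own residue and the linkage side chain.
#' @param label model label (`trimer`, `hexamer`, ...).
#' @return an object of class `environment_charges`.
#' @export
build_environment <- function(sources, chromophore, R, exclusions = NULL,
                              spec = NULL, label = "custom") {
  stopifnot(R >= 0)
  src <- as.data.frame(sources)
  if (is.null(src$source)) src$source <- "protein"
  if (is.null(src$origin)) {
    src$origin <- if (!is.null(src$atom_name)) {
      paste0(src$chain %||% "?", src$resno %||% "?", ":", src$atom_name)
    } else sprintf("charge%d", seq_len(nrow(src)))
  }
  if (!is.null(src$q) && any(abs(src$q) >= 2)) {
    stop("point charge magnitude >= 2 e looks unphysical")
  }
  keep <- rep(TRUE, nrow(src))
  if (!is.null(spec) && !is.null(src$chain) && !is.null(src$resno)) {
    keep <- keep & !(src$chain == spec$chain_id &
                       src$resno == spec$residue_number)
    if (!is.null(spec$linkage) && !is.null(src$atom_name)) {
      keep <- keep & !(src$chain == spec$linkage$chain &
                         src$resno == spec$linkage$resno &
                         src$atom_name %in% c("SG", "HG", "HSG"))
    }
  }
  for (ex in exclusions) {
    if (is.character(ex)) {
      if (!is.null(src$chain)) keep <- keep & src$chain != ex
    } else {
      keep <- keep & !(src$chain == ex$chain & src$resno == ex$resno)
    }
  }
  src <- src[keep, , drop = FALSE]
  cxyz <- frag_coords(chromophore)
  if (nrow(src)) {
    d <- pairwise_dist(as.matrix(src[, c("x", "y", "z")]), cxyz)
    dmin <- apply(d, 1, min)
    tooclose <- dmin < 0.5
    if (any(tooclose)) {
      warning(sum(tooclose), " point charge(s) within 0.5 Angstrom of a",
              " chromophore atom dropped")
    }
    src <- src[dmin <= R & !tooclose, , drop = FALSE]
  }
  rownames(src) <- NULL
  structure(list(
    charges = src[, intersect(c("x", "y", "z", "q", "source", "origin",
                                "chain", "resno", "atom_name"),
                              names(src)), drop = FALSE],
    radius = R,
    model_label = label,
    chromophore_id = if (!is.null(spec)) spec$chromophore_id
                     else chromophore$label,
    chromophore_centroid = colMeans(cxyz)),
    class = "environment_charges")
}

#' @export
print.environment_charges <- function(x, ...) {
  cat("<environment_charges> ", x$model_label, " around ",
      x$chromophore_id, "\n", sep = "")
  cat("  R =", x$radius, "Angstrom; ", nrow(x$charges), "charges;",
      " total q =", round(sum(x$charges$q), 4), "e\n")
  if (nrow(x$charges)) print(table(x$charges$source))
  invisible(x)
}

#' Neutralize an environment with counter ions
#'
#' Appends monovalent (+-1 e) point charges at seeded random positions on
#' a 12-15 Angstrom shell around the chromophore centroid until the
#' nearest integer to the total charge is zero.  Deterministic for a fixed
#' seed.
#'
#' @param environment an `environment_charges` object.
#' @param placement_seed integer seed.
#' @return the neutralized `environment_charges`.
#' @export
neutralize_with_counter_ions <- function(environment, placement_seed = 1) {
  tot <- sum(environment$charges$q)
  n_ions <- round(tot)
  if (n_ions == 0) return(environment)
  sgn <- -sign(n_ions)
  ctr <- environment$chromophore_centroid
  ions <- with_seed(placement_seed, {
    t(vapply(seq_len(abs(n_ions)), function(i) {
      dir <- stats::rnorm(3); dir <- dir / vnorm(dir)
      ctr + stats::runif(1, 12, 15) * dir
    }, numeric(3)))
  })
  add <- data.frame(x = ions[, 1], y = ions[, 2], z = ions[, 3],
                    q = sgn, source = "counter_ion",
                    origin = paste0("ion", seq_len(abs(n_ions))),
                    stringsAsFactors = FALSE)
  for (cn in setdiff(names(environment$charges), names(add))) {
    add[[cn]] <- NA
  }
  environment$charges <- rbind(environment$charges,
                               add[, names(environment$charges),
                                   drop = FALSE])
  environment
}

#' Write / read point-charge environments and charge tables as TSV
#'
#' @param environment an `environment_charges` object (or plain data
#'   frame of charges).
#' @param path file path.
#' @return `path` (writers, invisibly) or the read data frame.
#' @export
write_environment <- function(environment, path) {
  ch <- environment_charge_frame(environment)
  utils::write.table(ch, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname write_environment
#' @param charge_table charge table from [derive_residue_charges()].
#' @export
write_charge_table <- function(charge_table, path) {
  utils::write.table(charge_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_charge_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
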