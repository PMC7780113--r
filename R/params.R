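# Parameter handling for the semi-empirical engine.

.params_cache <- new.env(parent = emptyenv())

#' Semi-empirical INDO parameter set
#'
#' Loads the parameter set used by the SCF and CI engines: per-element
#' valence Slater exponents, resonance parameters, one-center
#' Coulomb/exchange integrals, the bond-type `k_beta` table of the
#' Wolfsberg-Helmholtz resonance integrals, the two-center repulsion
#' formula, and SCF/CI control settings.  The default set ships with the
#' package (`system.file("extdata", "indo_params.yaml", package =
#' "phycospec")`) and every field can be overridden.
#'
#' @param file path to a YAML parameter file; `NULL` uses the shipped
#'   default set.
#' @param ... named overrides merged over the file contents.  Nested lists
#'   are merged recursively, so `indo_params(scf = list(diis = FALSE))`
#'   changes only the DIIS switch.
#' @return an object of class `indo_params`.
#' @examples
#' p <- indo_params()
#' p$k_beta[["C-N"]]
#' p2 <- indo_params(ci = list(n_singles = 40))
#' @export
indo_params <- function(file = NULL, ...) {
  if (is.null(file)) {
    if (is.null(.params_cache$default)) {
      path <- system.file("extdata", "indo_params.yaml", package = "phycospec")
      if (!nzchar(path)) {
        # during development the package may not be installed yet
        path <- file.path("inst", "extdata", "indo_params.yaml")
      }
      .params_cache$default <- read_params_yaml(path)
    }
    p <- .params_cache$default
  } else {
    p <- read_params_yaml(file)
  }
  dots <- list(...)
  if (length(dots)) p <- modifyList(p, dots)
  validate_params(p)
  structure(p, class = "indo_params")
}

#' @keywords internal
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  p <- yaml::read_yaml(path)
  for (el in names(p$elements)) {
    p$elements[[el]]$has_p <- p$elements[[el]]$nshell > 1
  }
  p
}

#' @keywords internal
validate_params <- function(p) {
  stopifnot(is.list(p$elements), length(p$elements) > 0)
  for (el in names(p$elements)) {
    e <- p$elements[[el]]
    if (!is.numeric(e$zeta) || e$zeta <= 0) {
      stop("Slater exponent for ", el, " must be positive")
    }
  }
  if (!p$gamma_formula %in% c("mataga_nishimoto", "ohno")) {
    stop("gamma_formula must be 'mataga_nishimoto' or 'ohno'")
  }
  invisible(p)
}

#' Bond-type resonance scale factor
#'
#' Looks up the `k_beta` scale for an element pair; the lookup is symmetric
#' in the pair and falls back to the `other` entry.
#'
#' @param params an [indo_params()] object.
#' @param elA,elB element symbols.
#' @return numeric scale factor.
#' @examples
#' kb <- k_beta_lookup(indo_params(), "C", "N")
#' @export
k_beta_lookup <- function(params, elA, elB) {
  tab <- params$k_beta
  key1 <- paste(elA, elB, sep = "-")
  key2 <- paste(elB, elA, sep = "-")
  if (!is.null(tab[[key1]])) return(tab[[key1]])
  if (!is.null(tab[[key2]])) return(tab[[key2]])
  tab[["other"]]
}

#' Write a parameter set to YAML
#'
#' @param params an [indo_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  p <- unclass(params)
  for (el in names(p$elements)) p$elements[[el]]$has_p <- NULL
  yaml::write_yaml(p, path)
  invisible(path)
}

# Two-center electron-repulsion integral gamma_AB (eV) between the valence
# shells of two atoms at distance R (Angstrom).
#' @keywords internal
gamma_two_center <- function(gammaA, gammaB, R, formula) {
  a <- 2 * EV_ANGSTROM_COULOMB / (gammaA + gammaB)
  if (formula == "mataga_nishimoto") {
    EV_ANGSTROM_COULOMB / (R + a)
  } else {
    EV_ANGSTROM_COULOMB / sqrt(R * R + a * a)
  }
}

# Core one-electron energy U_mu_mu (eV) from the orbital electronegativity
# relation U = -(I+A)/2 - (Z_val - 1/2) * gamma_AA.
#' @keywords internal
u_core <- function(el, orbital, params) {
  e <- params$elements[[el]]
  zval <- .valence_electrons[[el]]
  half_ia <- if (orbital == "s") e$half_ia_s else e$half_ia_p
  -half_ia - (zval - 0.5) * e$gamma
}

# One-center two-electron tensor (nbf x nbf x nbf x nbf, eV) for an element,
# from the Slater-Condon parameters F0 (= gamma), G1, F2.  Orbital order
# s, px, py, pz (or s alone for hydrogen).
#' @keywords internal
one_center_tensor <- function(el, params) {
  e <- params$elements[[el]]
  F0 <- e$gamma
  if (!e$has_p) {
    return(array(F0, c(1, 1, 1, 1)))
  }
  G1 <- e$g1
  F2 <- e$f2
  t <- array(0, c(4, 4, 4, 4))
  s <- 1; p <- 2:4
  t[s, s, s, s] <- F0
  for (i in p) {
    t[s, s, i, i] <- F0
    t[i, i, s, s] <- F0
    t[s, i, s, i] <- G1 / 3
    t[i, s, i, s] <- G1 / 3
    t[s, i, i, s] <- G1 / 3
    t[i, s, s, i] <- G1 / 3
    t[i, i, i, i] <- F0 + 4 * F2 / 25
    for (j in p) {
      if (i != j) {
        t[i, i, j, j] <- F0 - 2 * F2 / 25
        t[i, j, i, j] <- 3 * F2 / 25
        t[i, j, j, i] <- 3 * F2 / 25
      }
    }
  }
  t
}
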