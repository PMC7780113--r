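# Closed-shell self-consistent-field engine in the INDO approximation.
#
# Valence-only minimal basis (H: 1s; C,N,O,S: s + 3p), zero-differential-
# overlap two-electron integrals (one-center Slater-Condon tensor, two-
# center Mataga-Nishimoto/Ohno gamma), Wolfsberg-Helmholtz resonance
# integrals over Slater-orbital overlaps scaled by bond-type k_beta, and
# one-electron embedding of external point charges as bare Coulomb shifts
# on the ZDO orbital centers.  All matrices are carried in eV.

# Basis bookkeeping: one row per basis function.
#' @keywords internal
basis_set <- function(fragment, params) {
  el <- fragment$atoms$element
  for (e in unique(el)) {
    if (is.null(params$elements[[e]])) {
      stop("element ", e, " is not parameterized")
    }
  }
  nbf_at <- ifelse(vapply(params$elements[el], `[[`, TRUE, "has_p"), 4L, 1L)
  atom_of <- rep(seq_along(el), nbf_at)
  orb <- unlist(lapply(nbf_at, function(n)
    if (n == 4L) c("s", "px", "py", "pz") else "s"))
  list(atom_of = atom_of, orbital = orb, nbf = length(atom_of),
       nbf_at = nbf_at, first = c(0L, cumsum(nbf_at))[seq_along(el)] + 1L)
}

# gamma_AB matrix over atoms (eV); diagonal = one-center F0.
#' @keywords internal
gamma_matrix <- function(fragment, params) {
  el <- fragment$atoms$element
  g0 <- vapply(params$elements[el], `[[`, 0, "gamma")
  xyz <- frag_coords(fragment)
  n <- length(el)
  G <- matrix(0, n, n)
  diag(G) <- g0
  if (n > 1) {
    D <- pairwise_dist(xyz, xyz)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        G[i, j] <- G[j, i] <-
          gamma_two_center(g0[i], g0[j], D[i, j], params$gamma_formula)
      }
    }
  }
  G
}

#' Core Hamiltonian and overlap matrix
#'
#' Builds the one-electron Hamiltonian: diagonal core terms `U_mumu`,
#' electron-core attraction `-Z_B gamma_AB` to all other atoms, the
#' external point-charge potential `-sum_k q_k / |R_A - r_k|` (bare
#' Coulomb, applied to every basis function of atom A), and two-center
#' resonance integrals `H_munu = 0.5 k_beta (beta_A + beta_B) S_munu`.
#' The scalar core-core and core-external repulsion is returned as an
#' energy offset.
#'
#' @param fragment a `fragment_geometry`.
#' @param params an [indo_params()] set.
#' @param environment an environment charge set from [build_environment()],
#'   a plain data frame with columns `x`, `y`, `z`, `q`, or `NULL` for
#'   vacuum.
#' @return list with `hcore` (eV), `overlap`, `e_nuclear` (eV), and the
#'   basis bookkeeping.
#' @export
build_core_hamiltonian <- function(fragment, params, environment = NULL) {
  bs <- basis_set(fragment, params)
  el <- fragment$atoms$element
  natom <- length(el)
  xyz <- frag_coords(fragment)
  G <- gamma_matrix(fragment, params)
  zval <- .valence_electrons[el]
  H <- matrix(0, bs$nbf, bs$nbf)
  S <- diag(bs$nbf)
  # diagonal core terms and electron-core attraction
  for (mu in seq_len(bs$nbf)) {
    A <- bs$atom_of[mu]
    orbkind <- if (bs$orbital[mu] == "s") "s" else "p"
    H[mu, mu] <- u_core(el[A], orbkind, params) -
      sum(zval[-A] * G[A, -A])
  }
  # external point charges: bare-Coulomb diagonal shift per atom
  v_ext <- numeric(natom)
  e_ext <- 0
  env <- environment_charge_frame(environment)
  if (!is.null(env) && nrow(env)) {
    d <- pairwise_dist(xyz, as.matrix(env[, c("x", "y", "z")]))
    if (any(d < 1e-6)) stop("external point charge coincides with an atom")
    v_ext <- as.numeric(d_inv <- (1 / d) %*% env$q) * EV_ANGSTROM_COULOMB
    for (mu in seq_len(bs$nbf)) {
      H[mu, mu] <- H[mu, mu] - v_ext[bs$atom_of[mu]]
    }
    e_ext <- sum(zval * v_ext)
  }
  # resonance integrals
  beta <- vapply(params$elements[el], `[[`, 0, "beta0")
  for (A in seq_len(natom - 1)) {
    for (B in (A + 1):natom) {
      Sblk <- overlap_block(el[A], el[B], xyz[A, ], xyz[B, ], params)
      Sres <- overlap_block(el[A], el[B], xyz[A, ], xyz[B, ], params,
                            weights = params$resonance_weights)
      kb <- k_beta_lookup(params, el[A], el[B])
      Hblk <- 0.5 * kb * (beta[A] + beta[B]) * Sres
      ia <- bs$first[A] + seq_len(bs$nbf_at[A]) - 1L
      ib <- bs$first[B] + seq_len(bs$nbf_at[B]) - 1L
      H[ia, ib] <- Hblk
      H[ib, ia] <- t(Hblk)
      S[ia, ib] <- Sblk
      S[ib, ia] <- t(Sblk)
    }
  }
  # scalar core-core repulsion (bare) + core-external interaction
  e_nuc <- e_ext
  if (natom > 1) {
    D <- pairwise_dist(xyz, xyz)
    for (A in seq_len(natom - 1)) {
      for (B in (A + 1):natom) {
        e_nuc <- e_nuc + EV_ANGSTROM_COULOMB * zval[A] * zval[B] / D[A, B]
      }
    }
  }
  list(hcore = H, overlap = S, e_nuclear = e_nuc, basis = bs, gamma = G)
}

# Accept an environment_charges object, a data frame, or NULL.
#' @keywords internal
environment_charge_frame <- function(environment) {
  if (is.null(environment)) return(NULL)
  if (inherits(environment, "environment_charges")) {
    return(environment$charges)
  }
  as.data.frame(environment)
}

# Two-electron part of the Fock matrix for density P.
#' @keywords internal
fock_two_electron <- function(P, bs, G, tensors) {
  nbf <- nrow(P)
  F2 <- matrix(0, nbf, nbf)
  # atom-summed densities
  p_at <- rowsum(diag(P), bs$atom_of)
  natom <- length(p_at)
  # two-center Coulomb on the diagonal, exchange on off-atom blocks
  Gz <- G; diag(Gz) <- 0
  coul <- as.numeric(Gz %*% p_at)
  same_atom <- outer(bs$atom_of, bs$atom_of, "==")
  gbf <- Gz[bs$atom_of, bs$atom_of]
  F2 <- -0.5 * P * gbf
  F2[same_atom] <- 0
  diag(F2) <- coul[bs$atom_of]
  # one-center Coulomb + exchange via the Slater-Condon tensor
  for (A in seq_len(natom)) {
    idx <- bs$first[A] + seq_len(bs$nbf_at[A]) - 1L
    TA <- tensors[[A]]
    PA <- P[idx, idx, drop = FALSE]
    nA <- length(idx)
    blk <- matrix(0, nA, nA)
    for (mu in seq_len(nA)) {
      for (nu in mu:nA) {
        v <- sum(TA[mu, nu, , ] * PA) - 0.5 * sum(TA[mu, , nu, ] * PA)
        blk[mu, nu] <- blk[nu, mu] <- v
      }
    }
    F2[idx, idx] <- F2[idx, idx] + blk
  }
  F2
}

#' Solve the closed-shell SCF equations
#'
#' Damped fixed-point iteration with optional DIIS acceleration.  The
#' initial guess occupies the eigenvectors of the core Hamiltonian.  The
#' run is deterministic for fixed input and parameters.
#'
#' @param fragment a `fragment_geometry` with an even electron count.
#' @param params an [indo_params()] set.
#' @param environment external point charges (see
#'   [build_core_hamiltonian()]).
#' @param diis override the DIIS switch in `params$scf` (pure damping when
#'   `FALSE`).
#' @return an object of class `indo_scf` with molecular-orbital
#'   coefficients, orbital energies (eV, ascending), the density matrix,
#'   electronic and total energies, atomic net charges, and the
#'   convergence trajectory.
#' @examples
#' h2 <- make_toy_molecule("water")
#' scf <- scf_solve(h2, indo_params())
#' scf$converged
#' @export
scf_solve <- function(fragment, params = indo_params(),
                      environment = NULL, diis = NULL) {
  nel <- n_electrons(fragment)
  if (nel %% 2 != 0) {
    stop("fragment has an odd electron count (", nel,
         "); closed-shell SCF requires an even count")
  }
  nocc <- nel %/% 2L
  core <- build_core_hamiltonian(fragment, params, environment)
  bs <- core$basis
  tensors <- lapply(fragment$atoms$element, one_center_tensor,
                    params = params)
  scf_opts <- params$scf
  use_diis <- if (is.null(diis)) isTRUE(scf_opts$diis) else isTRUE(diis)
  damping <- scf_opts$damping
  tol_e <- scf_opts$convergence_energy_au * EV_PER_HARTREE
  tol_p <- scf_opts$convergence_density_rms
  maxit <- scf_opts$max_iterations

  dens_from <- function(C) 2 * C[, seq_len(nocc), drop = FALSE] %*%
    t(C[, seq_len(nocc), drop = FALSE])
  eig <- eigen(core$hcore, symmetric = TRUE)
  ord <- order(eig$values)
  C <- eig$vectors[, ord, drop = FALSE]
  P <- dens_from(C)
  e_old <- Inf
  trajectory <- data.frame(iteration = integer(), energy_eV = numeric(),
                           density_rms = numeric())
  fock_hist <- list(); err_hist <- list()
  converged <- FALSE
  F <- NULL
  for (it in seq_len(maxit)) {
    F <- core$hcore + fock_two_electron(P, bs, core$gamma, tensors)
    e_elec <- 0.5 * sum(P * (core$hcore + F))
    if (use_diis) {
      err <- F %*% P - P %*% F
      fock_hist[[length(fock_hist) + 1]] <- F
      err_hist[[length(err_hist) + 1]] <- err
      if (length(fock_hist) > scf_opts$diis_size) {
        fock_hist <- fock_hist[-1]; err_hist <- err_hist[-1]
      }
      m <- length(fock_hist)
      if (m >= 2) {
        B <- matrix(0, m + 1, m + 1)
        for (i in seq_len(m)) {
          for (j in seq_len(m)) {
            B[i, j] <- sum(err_hist[[i]] * err_hist[[j]])
          }
        }
        B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
        rhs <- c(numeric(m), -1)
        cf <- tryCatch(solve(B, rhs)[seq_len(m)],
                       error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          F <- Reduce(`+`, Map(`*`, fock_hist, cf))
        }
      }
    }
    eig <- eigen(F, symmetric = TRUE)
    ord <- order(eig$values)
    C_new <- eig$vectors[, ord, drop = FALSE]
    eps <- eig$values[ord]
    P_raw <- dens_from(C_new)
    mix <- if (use_diis && length(fock_hist) >= 2) 0 else damping
    P_new <- mix * P + (1 - mix) * P_raw
    dP <- sqrt(mean((P_new - P)^2))
    trajectory <- rbind(trajectory,
                        data.frame(iteration = it, energy_eV = e_elec,
                                   density_rms = dP))
    de <- abs(e_elec - e_old)
    P <- P_new; C <- C_new; e_old <- e_elec
    if (de < tol_e && dP < tol_p) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("SCF did not converge in ", maxit, " iterations (last dE = ",
         format(de, digits = 3), " eV, dP rms = ",
         format(dP, digits = 3), ")")
  }
  # final consistent quantities from the idempotent density
  P <- dens_from(C)
  F <- core$hcore + fock_two_electron(P, bs, core$gamma, tensors)
  e_elec <- 0.5 * sum(P * (core$hcore + F))
  res <- structure(list(
    mo_coefficients = C,
    orbital_energies = eps,
    density = P,
    fock = F,
    electronic_energy_eV = e_elec,
    total_energy_eV = e_elec + core$e_nuclear,
    n_occupied = nocc,
    n_basis = bs$nbf,
    converged = converged,
    iterations = it,
    trajectory = trajectory,
    basis = bs,
    gamma = core$gamma,
    hcore = core$hcore,
    overlap = core$overlap,
    e_nuclear = core$e_nuclear,
    fragment = fragment,
    params = params),
    class = "indo_scf")
  res$atomic_net_charges <- atomic_charges(res, fragment)
  res
}

#' @export
print.indo_scf <- function(x, ...) {
  cat("<indo_scf> ", x$fragment$label, "\n", sep = "")
  cat("  basis functions:", x$n_basis, "  electrons:",
      2 * x$n_occupied, "\n")
  cat("  converged in", x$iterations, "iterations;  E(elec) =",
      format(x$electronic_energy_eV, digits = 10), "eV\n")
  gap <- x$orbital_energies[x$n_occupied + 1] -
    x$orbital_energies[x$n_occupied]
  cat("  HOMO-LUMO gap:", format(gap, digits = 5), "eV\n")
  invisible(x)
}

#' @export
summary.indo_scf <- function(object, ...) {
  print(object)
  cat("  atomic net charges (e):\n")
  q <- object$atomic_net_charges
  lab <- paste0(object$fragment$atoms$element,
                seq_len(n_atoms(object$fragment)))
  print(stats::setNames(round(q, 4), lab))
  invisible(object)
}

#' Atomic net charges from a converged SCF result
#'
#' ZDO population analysis: `q_A = Z_A(valence) - sum_(mu in A) P_mumu`.
#'
#' @param result an `indo_scf` object.
#' @param fragment the fragment the result was computed for (defaults to
#'   the one stored in the result).
#' @return numeric vector of per-atom net charges (e); sums to the
#'   fragment's total charge.
#' @export
atomic_charges <- function(result, fragment = result$fragment) {
  if (!isTRUE(result$converged)) {
    stop("refusing to analyze an unconverged SCF result")
  }
  zval <- .valence_electrons[fragment$atoms$element]
  pop <- rowsum(diag(result$density), result$basis$atom_of)
  as.numeric(zval - pop)
}
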