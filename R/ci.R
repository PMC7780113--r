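# Configuration interaction over the SCF reference: the lowest singlet
# single excitations psi(j,m) plus, optionally, the paired double
# excitations psi(jj,mm) that promote both electrons of phi_j to phi_m.
#
# Matrix elements are evaluated in the spin-adapted configuration basis
# with the ZDO two-electron integrals of the parameterization.  The
# default path uses closed-form expressions; a determinant-expansion
# engine (engine = "determinant") provides an internally independent
# construction used for cross-checks.

#' Enumerate CI configurations
#'
#' Singles are ranked by the zeroth-order gap `eps_m - eps_j` (ascending),
#' ties broken by smaller virtual index then larger occupied index; the
#' first `n_singles` are kept.  With `include_paired_doubles` the paired
#' double `psi(jj,mm)` of every kept single is appended, giving
#' `2 * n_singles` configurations.
#'
#' @param scf a converged `indo_scf` result.
#' @param n_singles number of single excitations to keep (default 169).
#' @param include_paired_doubles append the paired doubles?
#' @return data frame with columns `kind` (`single` or `paired_double`),
#'   `j`, `m`, `gap_eV`.
#' @export
enumerate_configurations <- function(scf, n_singles = 169,
                                     include_paired_doubles = TRUE) {
  stopifnot(isTRUE(scf$converged))
  nocc <- scf$n_occupied
  nvirt <- scf$n_basis - nocc
  if (nvirt < 1) stop("no virtual orbitals available")
  pairs <- expand.grid(j = seq_len(nocc),
                       m = nocc + seq_len(nvirt))
  gap <- scf$orbital_energies[pairs$m] - scf$orbital_energies[pairs$j]
  ord <- order(gap, pairs$m, -pairs$j)
  if (nrow(pairs) < n_singles) {
    warning("only ", nrow(pairs), " excitation pairs exist; using all")
    n_singles <- nrow(pairs)
  }
  keep <- ord[seq_len(n_singles)]
  singles <- data.frame(kind = "single", j = pairs$j[keep],
                        m = pairs$m[keep], gap_eV = gap[keep],
                        stringsAsFactors = FALSE)
  if (include_paired_doubles) {
    doubles <- singles
    doubles$kind <- "paired_double"
    rbind(singles, doubles)
  } else {
    singles
  }
}

# ---- ZDO molecular-orbital two-electron integrals ----------------------

# Machinery for (pq|rs) over MO pairs: atom-condensed transition charges
# handle the two-center gamma part; per-atom Slater-Condon tensors supply
# the one-center Coulomb/exchange structure.
#' @keywords internal
eri_context <- function(scf) {
  bs <- scf$basis
  frag <- scf$fragment
  params <- scf$params
  natom <- n_atoms(frag)
  tensors <- lapply(frag$atoms$element, one_center_tensor, params = params)
  Tmats <- lapply(tensors, function(t) {
    n2 <- dim(t)[1]^2
    matrix(t, n2, n2)
  })
  Gz <- scf$gamma
  diag(Gz) <- 0
  list(C = scf$mo_coefficients, bs = bs, natom = natom, Gz = Gz,
       Tmats = Tmats)
}

# pairs: 2-column matrix of MO indices.  Returns list(Q, W) where Q is
# npair x natom atom-condensed products and W stacks vec(c_p c_q^T) per
# atom block.
#' @keywords internal
eri_pair_data <- function(ctx, pairs) {
  C <- ctx$C
  bs <- ctx$bs
  CC <- C[, pairs[, 1], drop = FALSE] * C[, pairs[, 2], drop = FALSE]
  Q <- t(rowsum(CC, bs$atom_of))
  W <- vector("list", ctx$natom)
  for (A in seq_len(ctx$natom)) {
    idx <- bs$first[A] + seq_len(bs$nbf_at[A]) - 1L
    nA <- length(idx)
    Cp <- C[idx, pairs[, 1], drop = FALSE]
    Cq <- C[idx, pairs[, 2], drop = FALSE]
    W[[A]] <- Cp[rep(seq_len(nA), times = nA), , drop = FALSE] *
      Cq[rep(seq_len(nA), each = nA), , drop = FALSE]
  }
  list(Q = Q, W = W)
}

# ERI matrix between two pair lists: M[s, t] = (p_s q_s | r_t s_t), eV.
#' @keywords internal
eri_matrix <- function(ctx, pd1, pd2) {
  M <- pd1$Q %*% ctx$Gz %*% t(pd2$Q)
  for (A in seq_len(ctx$natom)) {
    M <- M + t(pd1$W[[A]]) %*% ctx$Tmats[[A]] %*% pd2$W[[A]]
  }
  M
}

#' Build the CI matrix
#'
#' Assembles the Hermitian CI Hamiltonian (eV, relative to the SCF
#' reference energy) over the basis `{ground state} + configs`.  Singles
#' are singlet spin-adapted; the ground-state row couples only to the
#' paired doubles (its coupling to singles vanishes by Brillouin's theorem
#' and is enforced to zero).
#'
#' @param configs configuration table from [enumerate_configurations()].
#' @param scf the `indo_scf` result the configurations refer to.
#' @param engine `"formula"` (closed-form matrix elements, default) or
#'   `"determinant"` (explicit determinant expansion; slower, used for
#'   cross-validation).
#' @return symmetric matrix of dimension `1 + nrow(configs)`.
#' @export
build_ci_matrix <- function(configs, scf, engine = c("formula",
                                                     "determinant")) {
  engine <- match.arg(engine)
  nocc <- scf$n_occupied
  if (any(configs$j > nocc | configs$m <= nocc | configs$j < 1 |
            configs$m > scf$n_basis)) {
    stop("configuration index out of range: consistency error")
  }
  if (engine == "determinant") {
    return(ci_matrix_determinant(configs, scf))
  }
  eps <- scf$orbital_energies
  S <- configs[configs$kind == "single", , drop = FALSE]
  D <- configs[configs$kind == "paired_double", , drop = FALSE]
  nS <- nrow(S); nD <- nrow(D)
  dim_ci <- 1L + nS + nD
  H <- matrix(0, dim_ci, dim_ci)
  ctx <- eri_context(scf)
  js <- sort(unique(configs$j))
  ms <- sort(unique(configs$m))
  # pair universes
  ov_pairs <- cbind(configs$j, configs$m)
  ov_pairs <- unique(ov_pairs)
  oo_pairs <- cbind(rep(js, each = length(js)),
                    rep(js, times = length(js)))
  oo_pairs <- unique(t(apply(oo_pairs, 1, sort)))
  vv_pairs <- cbind(rep(ms, each = length(ms)),
                    rep(ms, times = length(ms)))
  vv_pairs <- unique(t(apply(vv_pairs, 1, sort)))
  # lookup tables from (a, b) to row index
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ov_idx <- stats::setNames(seq_len(nrow(ov_pairs)),
                            paste(ov_pairs[, 1], ov_pairs[, 2]))
  oo_idx <- stats::setNames(seq_len(nrow(oo_pairs)),
                            paste(oo_pairs[, 1], oo_pairs[, 2]))
  vv_idx <- stats::setNames(seq_len(nrow(vv_pairs)),
                            paste(vv_pairs[, 1], vv_pairs[, 2]))
  pd_ov <- eri_pair_data(ctx, ov_pairs)
  pd_oo <- eri_pair_data(ctx, oo_pairs)
  pd_vv <- eri_pair_data(ctx, vv_pairs)
  M_ovov <- eri_matrix(ctx, pd_ov, pd_ov)
  M_oovv <- eri_matrix(ctx, pd_oo, pd_vv)
  M_ovoo <- eri_matrix(ctx, pd_ov, pd_oo)
  M_ovvv <- eri_matrix(ctx, pd_ov, pd_vv)
  # diagonals (pq|pq) of the OO and VV pair lists
  K_oo <- diag(eri_matrix(ctx, pd_oo, pd_oo))
  K_vv <- diag(eri_matrix(ctx, pd_vv, pd_vv))
  s_ov <- ov_idx[paste(S$j, S$m)]
  d_ov <- if (nD) ov_idx[paste(D$j, D$m)] else integer()
  # singles block: delta * (eps_m - eps_j) + 2 (jm|kn) - (jk|mn)
  if (nS) {
    roo <- matrix(oo_idx[key(rep(S$j, each = nS), rep(S$j, times = nS))],
                  nS, nS, byrow = TRUE)
    rvv <- matrix(vv_idx[key(rep(S$m, each = nS), rep(S$m, times = nS))],
                  nS, nS, byrow = TRUE)
    blk <- 2 * M_ovov[s_ov, s_ov, drop = FALSE] -
      matrix(M_oovv[cbind(as.vector(roo), as.vector(rvv))], nS, nS)
    diag(blk) <- diag(blk) + (eps[S$m] - eps[S$j])
    H[1 + seq_len(nS), 1 + seq_len(nS)] <- blk
  }
  if (nD) {
    dd <- 1 + nS + seq_len(nD)
    # ground state couples to each paired double through (jm|jm)
    H[1, dd] <- H[dd, 1] <- M_ovov[cbind(d_ov, d_ov)]
    # doubles diagonal:
    # 2(eps_m - eps_j) + (jj|jj) + (mm|mm) - 4(jj|mm) + 2(jm|jm)
    joo <- oo_idx[key(D$j, D$j)]
    mvv <- vv_idx[key(D$m, D$m)]
    diagD <- 2 * (eps[D$m] - eps[D$j]) + K_oo[joo] + K_vv[mvv] -
      4 * M_oovv[cbind(joo, mvv)] + 2 * M_ovov[cbind(d_ov, d_ov)]
    H[cbind(dd, dd)] <- diagD
    # doubles-doubles off-diagonal
    if (nD > 1) {
      for (a in seq_len(nD - 1)) {
        for (b in (a + 1):nD) {
          if (D$j[a] == D$j[b] && D$m[a] != D$m[b]) {
            v <- K_vv[vv_idx[key(D$m[a], D$m[b])]]
          } else if (D$m[a] == D$m[b] && D$j[a] != D$j[b]) {
            v <- K_oo[oo_idx[key(D$j[a], D$j[b])]]
          } else {
            v <- 0
          }
          H[dd[a], dd[b]] <- H[dd[b], dd[a]] <- v
        }
      }
    }
    # singles-doubles coupling
    if (nS) {
      for (s in seq_len(nS)) {
        k <- S$j[s]; n <- S$m[s]
        for (d in seq_len(nD)) {
          j <- D$j[d]; m <- D$m[d]
          if (k == j && n == m) {
            v <- sqrt(2) * (M_ovvv[ov_idx[paste(j, m)],
                                   vv_idx[key(m, m)]] -
                              M_ovoo[ov_idx[paste(j, m)],
                                     oo_idx[key(j, j)]])
          } else if (k == j && n != m) {
            v <- sqrt(2) * M_ovvv[ov_idx[paste(j, m)], vv_idx[key(n, m)]]
          } else if (n == m && k != j) {
            v <- -sqrt(2) * M_ovoo[ov_idx[paste(j, m)], oo_idx[key(j, k)]]
          } else {
            v <- 0
          }
          H[1 + s, 1 + nS + d] <- H[1 + nS + d, 1 + s] <- v
        }
      }
    }
  }
  H
}

# ---- determinant expansion engine --------------------------------------

# Spin orbitals: spatial p with alpha -> 2p-1, beta -> 2p.
#' @keywords internal
so_spatial <- function(k) (k + 1L) %/% 2L
#' @keywords internal
so_spin <- function(k) k %% 2L  # 1 = alpha, 0 = beta

# Apply a+_p a_q to a sorted determinant; returns list(det, sign) or NULL.
#' @keywords internal
det_excite <- function(det, p, q) {
  iq <- match(q, det)
  if (is.na(iq)) return(NULL)
  sgn <- (-1)^(iq - 1)
  d <- det[-iq]
  if (p %in% d) return(NULL)
  np <- sum(d < p)
  sgn <- sgn * (-1)^np
  list(det = sort(c(d, p)), sign = sgn)
}

# CSF expansion for the ground state + configuration table.
#' @keywords internal
csf_expansion <- function(configs, nocc) {
  ref <- sort(c(2L * seq_len(nocc) - 1L, 2L * seq_len(nocc)))
  csfs <- vector("list", 1L + nrow(configs))
  csfs[[1]] <- list(dets = list(ref), coefs = 1)
  for (i in seq_len(nrow(configs))) {
    j <- configs$j[i]; m <- configs$m[i]
    if (configs$kind[i] == "single") {
      ea <- det_excite(ref, 2L * m - 1L, 2L * j - 1L)
      eb <- det_excite(ref, 2L * m, 2L * j)
      csfs[[1 + i]] <- list(dets = list(ea$det, eb$det),
                            coefs = c(ea$sign, eb$sign) / sqrt(2))
    } else {
      eb <- det_excite(ref, 2L * m, 2L * j)
      ea <- det_excite(eb$det, 2L * m - 1L, 2L * j - 1L)
      csfs[[1 + i]] <- list(dets = list(ea$det),
                            coefs = eb$sign * ea$sign)
    }
  }
  csfs
}

# Full ERI lookup structure over a set of spatial orbitals.
#' @keywords internal
eri_universe <- function(scf, orbitals) {
  ctx <- eri_context(scf)
  u <- sort(unique(orbitals))
  nu <- length(u)
  pairs <- cbind(rep(u, each = nu), rep(u, times = nu))
  pairs <- unique(t(apply(pairs, 1, sort)))
  pd <- eri_pair_data(ctx, pairs)
  M <- eri_matrix(ctx, pd, pd)
  idx <- matrix(NA_integer_, max(u), max(u))
  for (r in seq_len(nrow(pairs))) {
    idx[pairs[r, 1], pairs[r, 2]] <- r
    idx[pairs[r, 2], pairs[r, 1]] <- r
  }
  h_mo <- t(scf$mo_coefficients) %*% scf$hcore %*% scf$mo_coefficients
  list(M = M, idx = idx, h = h_mo)
}

#' @keywords internal
eri_get <- function(uni, p, q, r, s) {
  uni$M[uni$idx[p, q], uni$idx[r, s]]
}

# Slater-Condon matrix element <d1|H|d2> (eV) for sorted spin-orbital
# determinants.
#' @keywords internal
slater_condon <- function(d1, d2, uni) {
  a <- setdiff(d1, d2)
  b <- setdiff(d2, d1)
  nd <- length(a)
  if (nd > 2) return(0)
  sp <- so_spatial; sn <- so_spin
  if (nd == 0) {
    p <- sp(d1); s <- sn(d1)
    e <- sum(uni$h[cbind(p, p)])
    for (i in seq_along(d1)) {
      for (j in seq_along(d1)) {
        if (i < j) {
          e <- e + eri_get(uni, p[i], p[i], p[j], p[j])
          if (s[i] == s[j]) e <- e - eri_get(uni, p[i], p[j], p[i], p[j])
        }
      }
    }
    return(e)
  }
  if (nd == 1) {
    if (sn(a) != sn(b)) return(0)
    sgn <- (-1)^(match(a, d1) + match(b, d2))
    common <- intersect(d1, d2)
    v <- uni$h[sp(a), sp(b)]
    for (c in common) {
      v <- v + eri_get(uni, sp(a), sp(b), sp(c), sp(c))
      if (sn(c) == sn(a)) {
        v <- v - eri_get(uni, sp(a), sp(c), sp(b), sp(c))
      }
    }
    return(sgn * v)
  }
  # nd == 2
  a <- sort(a); b <- sort(b)
  sgn <- (-1)^(match(a[1], d1) + match(a[2], d1) +
                 match(b[1], d2) + match(b[2], d2))
  v <- 0
  if (sn(a[1]) == sn(b[1]) && sn(a[2]) == sn(b[2])) {
    v <- v + eri_get(uni, sp(a[1]), sp(b[1]), sp(a[2]), sp(b[2]))
  }
  if (sn(a[1]) == sn(b[2]) && sn(a[2]) == sn(b[1])) {
    v <- v - eri_get(uni, sp(a[1]), sp(b[2]), sp(a[2]), sp(b[1]))
  }
  sgn * v
}

#' @keywords internal
ci_matrix_determinant <- function(configs, scf) {
  nocc <- scf$n_occupied
  csfs <- csf_expansion(configs, nocc)
  uni <- eri_universe(scf, c(seq_len(nocc), unique(configs$m)))
  n <- length(csfs)
  ref <- csfs[[1]]$dets[[1]]
  e0 <- slater_condon(ref, ref, uni)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- 0
      ci_ <- csfs[[i]]; cj <- csfs[[j]]
      for (a in seq_along(ci_$dets)) {
        for (b in seq_along(cj$dets)) {
          v <- v + ci_$coefs[a] * cj$coefs[b] *
            slater_condon(ci_$dets[[a]], cj$dets[[b]], uni)
        }
      }
      if (i == j) v <- v - e0
      H[i, j] <- H[j, i] <- v
    }
  }
  # enforce Brillouin exactly on the ground-state row
  singles <- which(configs$kind == "single")
  H[1, 1 + singles] <- H[1 + singles, 1] <- 0
  H
}

#' Diagonalize the CI matrix
#'
#' @param ci_matrix symmetric CI matrix from [build_ci_matrix()].
#' @return list with `excitation_energies_eV` (sorted ascending, relative
#'   to the CI ground state), `vectors` (columns; first column is the CI
#'   ground state), and `ground_energy_eV` (relative to the SCF
#'   reference).
#' @export
solve_states <- function(ci_matrix) {
  if (max(abs(ci_matrix - t(ci_matrix))) > 1e-8) {
    stop("CI matrix is not symmetric")
  }
  eig <- eigen(ci_matrix, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  list(excitation_energies_eV = vals[-1] - vals[1],
       vectors = vecs,
       ground_energy_eV = vals[1])
}
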