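# Independent numerical oracles used by the tests.

# Numeric overlap between two Slater orbitals by 2-D adaptive quadrature
# in spherical coordinates around atom A (axis along A->B).  l = 0 (s) or
# 1 with m = 0 (sigma); pi-pi overlap handled via the analytic phi
# integral.
numeric_sto_overlap <- function(nA, lA, nB, lB, zA, zB, R,
                                pi_channel = FALSE) {
  Nr <- function(n, z) (2 * z)^(n + 0.5) / sqrt(factorial(2 * n))
  f <- function(r, th) {
    rB <- sqrt(r^2 + R^2 - 2 * r * R * cos(th))
    cthB <- (r * cos(th) - R) / rB
    sthA <- sin(th)
    sthB <- sqrt(pmax(1 - cthB^2, 0))
    if (pi_channel) {
      angA <- sqrt(3 / (4 * pi)) * sthA
      angB <- sqrt(3 / (4 * pi)) * sthB
      phi_int <- pi
    } else {
      angA <- if (lA == 0) 1 / sqrt(4 * pi) else
        sqrt(3 / (4 * pi)) * cos(th)
      angB <- if (lB == 0) 1 / sqrt(4 * pi) else
        sqrt(3 / (4 * pi)) * cthB
      phi_int <- 2 * pi
    }
    Nr(nA, zA) * r^(nA - 1) * exp(-zA * r) * angA *
      Nr(nB, zB) * rB^(nB - 1) * exp(-zB * rB) * angB * r^2 * sin(th) *
      phi_int / (2 * pi)
  }
  2 * pi * stats::integrate(Vectorize(function(th) {
    stats::integrate(function(r) f(r, th), 0, 50,
                     rel.tol = 1e-10)$value
  }), 0, pi, rel.tol = 1e-9)$value
}

# ---- Jordan-Wigner Fock-space oracle -----------------------------------
# Builds the many-electron Hamiltonian as an explicit matrix over the full
# Fock space of 2*nbf spin orbitals, from the package's one-electron and
# ZDO two-electron integrals, with no reference to Slater-Condon rules.
# Feasible for nbf <= 5.

jw_ops <- function(nso) {
  requireNamespace("Matrix", quietly = TRUE)
  A <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2))
  Z <- Matrix::Diagonal(x = c(1, -1))
  I2 <- Matrix::Diagonal(2)
  op_a <- function(k) {
    m <- Matrix::Diagonal(1)
    for (f in 1:nso) {
      m <- Matrix::kronecker(if (f < k) Z else if (f == k) A else I2, m)
    }
    m
  }
  a <- lapply(1:nso, op_a)
  list(a = a, ad = lapply(a, Matrix::t))
}

jw_hamiltonian <- function(scf) {
  nbf <- scf$n_basis
  nso <- 2L * nbf
  uni <- phycospec:::eri_universe(scf, seq_len(nbf))
  ops <- jw_ops(nso)
  sp <- function(k) (k + 1L) %/% 2L
  ss <- function(k) k %% 2L
  dim_f <- 2^nso
  # precompute number-conserving quadratic blocks N_PQ = a+_P a_Q
  Npq <- vector("list", nso * nso)
  getN <- function(P, Q) {
    id <- (P - 1L) * nso + Q
    if (is.null(Npq[[id]])) Npq[[id]] <<- ops$ad[[P]] %*% ops$a[[Q]]
    Npq[[id]]
  }
  H <- Matrix::Matrix(0, dim_f, dim_f, sparse = TRUE)
  for (P in 1:nso) for (Q in 1:nso) {
    if (ss(P) != ss(Q)) next
    v <- uni$h[sp(P), sp(Q)]
    if (abs(v) > 1e-14) H <- H + v * getN(P, Q)
  }
  # a+_P a+_R a_S a_Q = N_PQ N_RS - delta_QR N_PS
  for (P in 1:nso) for (Q in 1:nso) {
    if (ss(P) != ss(Q)) next
    for (R in 1:nso) for (S in 1:nso) {
      if (ss(R) != ss(S)) next
      v <- phycospec:::eri_get(uni, sp(P), sp(Q), sp(R), sp(S))
      if (abs(v) < 1e-14) next
      term <- getN(P, Q) %*% getN(R, S)
      if (Q == R) term <- term - getN(P, S)
      H <- H + 0.5 * v * term
    }
  }
  list(H = H, ops = ops, nso = nso)
}

jw_det_vector <- function(jw, det) {
  v <- Matrix::Matrix(0, 2^jw$nso, 1)
  v[1, 1] <- 1
  for (k in rev(sort(det))) v <- jw$ops$ad[[k]] %*% v
  v
}

# CI matrix over the package's CSF basis, evaluated in the JW Fock space.
jw_csf_matrix <- function(jw, configs, nocc) {
  csfs <- phycospec:::csf_expansion(configs, nocc)
  vecs <- lapply(csfs, function(cs) {
    v <- Matrix::Matrix(0, 2^jw$nso, 1)
    for (a in seq_along(cs$dets)) {
      v <- v + cs$coefs[a] * jw_det_vector(jw, cs$dets[[a]])
    }
    v
  })
  n <- length(vecs)
  M <- matrix(0, n, n)
  hv <- lapply(vecs, function(v) jw$H %*% v)
  for (i in 1:n) for (j in i:n) {
    M[i, j] <- M[j, i] <- as.numeric(Matrix::t(vecs[[i]]) %*% hv[[j]])
  }
  M - diag(M[1, 1], n)
}

# Eigenvalues of the JW Hamiltonian restricted to the span of the
# reference + all singly excited determinants (Sz = 0 sector).
jw_singles_space_energies <- function(jw, nocc, nbf) {
  ref <- sort(c(2L * seq_len(nocc) - 1L, 2L * seq_len(nocc)))
  dets <- list(ref)
  for (j in seq_len(nocc)) {
    for (m in (nocc + 1):nbf) {
      ea <- phycospec:::det_excite(ref, 2L * m - 1L, 2L * j - 1L)
      eb <- phycospec:::det_excite(ref, 2L * m, 2L * j)
      dets <- c(dets, list(ea$det), list(eb$det))
    }
  }
  vecs <- lapply(dets, function(d) jw_det_vector(jw, d))
  n <- length(vecs)
  M <- matrix(0, n, n)
  hv <- lapply(vecs, function(v) jw$H %*% v)
  for (i in 1:n) for (j in i:n) {
    M[i, j] <- M[j, i] <- as.numeric(Matrix::t(vecs[[i]]) %*% hv[[j]])
  }
  sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}
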