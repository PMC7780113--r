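# Overlap integrals between Slater-type valence orbitals.
#
# The resonance part of the one-electron Hamiltonian needs <mu|nu> between
# STOs on different centers.  Integrals are evaluated analytically in
# prolate spheroidal coordinates: the integrand reduces to a polynomial in
# (mu, nu) times exp(-p*mu - q*nu), so every overlap is a finite sum of
# auxiliary integrals A_k(p) = int_1^Inf x^k e^(-p x) dx and
# B_k(q) = int_-1^1 x^k e^(-q x) dx (Mulliken's method).  Supported shells:
# ns and np for n = 1..3, which covers H(1s), C/N/O(2s2p), S(3s3p).

aux_A <- function(kmax, p) {
  # A_k(p) for k = 0..kmax; A_k = e^-p * sum_{i=0..k} k!/(k-i)! / p^(i+1)
  ks <- 0:kmax
  vapply(ks, function(k) {
    i <- 0:k
    exp(-p) * sum(exp(lfactorial(k) - lfactorial(k - i)) / p^(i + 1))
  }, numeric(1))
}

aux_B <- function(kmax, q) {
  # B_k(q) for k = 0..kmax.  Power series for small |q| (the closed form
  # cancels catastrophically), upward recurrence otherwise.
  if (abs(q) < 2) {
    vapply(0:kmax, function(k) {
      s <- 0:40
      term <- (-q)^s / factorial(s)
      even <- (k + s) %% 2 == 0
      sum(term[even] * 2 / (k + s[even] + 1))
    }, numeric(1))
  } else {
    B <- numeric(kmax + 1)
    B[1] <- 2 * sinh(q) / q
    if (kmax >= 1) {
      for (k in 1:kmax) {
        B[k + 1] <- (((-1)^k) * exp(q) - exp(-q)) / q + (k / q) * B[k]
      }
    }
    B
  }
}

# -- tiny bivariate polynomial algebra: coefficient matrices over mu^i nu^j --

poly_const <- function(x = 1) matrix(x, 1, 1)

poly_mul <- function(a, b) {
  out <- matrix(0, nrow(a) + nrow(b) - 1, ncol(a) + ncol(b) - 1)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] != 0) {
        out[i:(i + nrow(b) - 1), j:(j + ncol(b) - 1)] <-
          out[i:(i + nrow(b) - 1), j:(j + ncol(b) - 1)] + a[i, j] * b
      }
    }
  }
  out
}

poly_pow <- function(a, k) {
  out <- poly_const(1)
  if (k > 0) for (i in seq_len(k)) out <- poly_mul(out, a)
  out
}

.p_mu_plus_nu  <- matrix(c(0, 1, 1, 0), 2, 2)   # mu + nu
.p_mu_minus_nu <- matrix(c(0, 1, -1, 0), 2, 2)  # mu - nu
.p_one_plus_munu  <- matrix(c(1, 0, 0, 1), 2, 2)   # 1 + mu*nu
.p_munu_minus_one <- matrix(c(-1, 0, 0, 1), 2, 2)  # mu*nu - 1
# (mu^2 - 1)(1 - nu^2)
.p_pipi <- poly_mul(matrix(c(-1, 0, 1), 3, 1), matrix(c(1, 0, -1), 1, 3))

#' Overlap between two Slater orbitals in the diatomic frame
#'
#' Computes `<n_A l_A | n_B l_B>` for orbitals aligned in the local diatomic
#' frame with the z axis pointing from atom A to atom B; `type` selects the
#' symmetry channel.
#'
#' @param nA,nB principal quantum numbers (1-3).
#' @param zetaA,zetaB Slater exponents in bohr^-1.
#' @param R internuclear distance in bohr.
#' @param type one of `"ss"`, `"s_psigma"`, `"psigma_s"`, `"psigma_psigma"`,
#'   `"ppi_ppi"`.
#' @return the overlap integral (dimensionless).
#' @keywords internal
sto_pair_overlap <- function(nA, nB, zetaA, zetaB, R, type) {
  stopifnot(R > 0)
  p <- R * (zetaA + zetaB) / 2
  q <- R * (zetaA - zetaB) / 2
  # radial normalizations (2 zeta)^(n + 1/2) / sqrt((2n)!)
  Nrad <- function(n, z) (2 * z)^(n + 0.5) / sqrt(factorial(2 * n))
  base <- poly_mul(poly_pow(.p_mu_plus_nu, nA - 1),
                   poly_pow(.p_mu_minus_nu, nB - 1))
  dv <- poly_mul(.p_mu_plus_nu, .p_mu_minus_nu)
  if (type == "ss") {
    poly <- poly_mul(base, dv)
    ang <- (1 / (4 * pi)) * 2 * pi
  } else if (type == "s_psigma") {
    poly <- poly_mul(poly_mul(base, .p_mu_plus_nu), .p_munu_minus_one)
    ang <- (sqrt(3) / (4 * pi)) * 2 * pi
  } else if (type == "psigma_s") {
    poly <- poly_mul(poly_mul(base, .p_one_plus_munu), .p_mu_minus_nu)
    ang <- (sqrt(3) / (4 * pi)) * 2 * pi
  } else if (type == "psigma_psigma") {
    poly <- poly_mul(poly_mul(base, .p_one_plus_munu), .p_munu_minus_one)
    ang <- (3 / (4 * pi)) * 2 * pi
  } else if (type == "ppi_ppi") {
    poly <- poly_mul(base, .p_pipi)
    ang <- (3 / (4 * pi)) * pi
  } else {
    stop("unknown overlap type: ", type)
  }
  A <- aux_A(nrow(poly) - 1, p)
  B <- aux_B(ncol(poly) - 1, q)
  s <- 0
  for (i in seq_len(nrow(poly))) {
    nz <- which(poly[i, ] != 0)
    if (length(nz)) s <- s + sum(poly[i, nz] * B[nz]) * A[i]
  }
  Nrad(nA, zetaA) * Nrad(nB, zetaB) * ang * (R / 2)^(nA + nB + 1) * s
}

#' Overlap block between the valence shells of two atoms
#'
#' Returns the matrix of overlaps between all valence orbitals on atom A
#' (rows) and atom B (columns), in the molecular frame.  Orbital order is
#' `s` for hydrogen and `s, px, py, pz` otherwise.  Local sigma/pi overlaps
#' are rotated with the direction cosines of the A->B axis.
#'
#' @param elA,elB element symbols.
#' @param rA,rB positions in Angstrom.
#' @param params parameter set from [indo_params()].
#' @param weights optional list with `sigma_pp` and `pi_pp` channel
#'   weights applied to the p-p overlaps (used for the spectroscopic
#'   resonance integrals; the plain overlap uses `NULL`).
#' @return numeric overlap matrix.
#' @keywords internal
overlap_block <- function(elA, elB, rA, rB, params, weights = NULL) {
  eA <- params$elements[[elA]]
  eB <- params$elements[[elB]]
  d <- (rB - rA) * BOHR_PER_ANGSTROM
  R <- vnorm(d)
  u <- d / R
  nA <- eA$nshell; nB <- eB$nshell
  zA <- eA$zeta;   zB <- eB$zeta
  hasP_A <- eA$has_p; hasP_B <- eB$has_p
  dimA <- if (hasP_A) 4L else 1L
  dimB <- if (hasP_B) 4L else 1L
  S <- matrix(0, dimA, dimB)
  S[1, 1] <- sto_pair_overlap(nA, nB, zA, zB, R, "ss")
  if (hasP_B) {
    ssig <- sto_pair_overlap(nA, nB, zA, zB, R, "s_psigma")
    S[1, 2:4] <- ssig * u
  }
  if (hasP_A) {
    psig <- sto_pair_overlap(nA, nB, zA, zB, R, "psigma_s")
    S[2:4, 1] <- psig * u
  }
  if (hasP_A && hasP_B) {
    sigsig <- sto_pair_overlap(nA, nB, zA, zB, R, "psigma_psigma")
    pipi <- sto_pair_overlap(nA, nB, zA, zB, R, "ppi_ppi")
    if (!is.null(weights)) {
      sigsig <- sigsig * weights$sigma_pp
      pipi <- pipi * weights$pi_pp
    }
    S[2:4, 2:4] <- sigsig * (u %o% u) + pipi * (diag(3) - u %o% u)
  }
  S
}
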