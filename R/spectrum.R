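# Excited-state spectra: CI states with wavelengths and oscillator
# strengths in the ZDO point-charge (atom-condensed) dipole approximation.

# Precomputed one-particle transition machinery for a configuration set:
# determinant pair "triplets" (bra det, ket det, p, q, sign) for
# <d1|E_pq|d2> plus per-determinant diagonal dipole sums.
#' @keywords internal
tdm_context <- function(configs, scf) {
  nocc <- scf$n_occupied
  csfs <- csf_expansion(configs, nocc)
  ncsf <- length(csfs)
  dets <- list(); owner <- integer(); dcoef <- numeric()
  for (i in seq_len(ncsf)) {
    for (a in seq_along(csfs[[i]]$dets)) {
      dets[[length(dets) + 1]] <- csfs[[i]]$dets[[a]]
      owner <- c(owner, i)
      dcoef <- c(dcoef, csfs[[i]]$coefs[a])
    }
  }
  nd <- length(dets)
  nso <- 2L * scf$n_basis
  occm <- matrix(0L, nd, nso)
  for (d in seq_len(nd)) occm[d, dets[[d]]] <- 1L
  nel <- length(dets[[1]])
  common <- tcrossprod(occm)
  cand <- which(common == nel - 1L, arr.ind = TRUE)
  # MO-basis dipole matrices, atom-condensed (ZDO), origin at the nuclear
  # charge centroid; units e * Angstrom before conversion
  frag <- scf$fragment
  xyz <- frag_coords(frag)
  zv <- .valence_electrons[frag$atoms$element]
  orig <- colSums(xyz * zv) / sum(zv)
  C <- scf$mo_coefficients
  ax <- xyz[scf$basis$atom_of, , drop = FALSE]
  dip <- lapply(1:3, function(k) t(C) %*% (C * (ax[, k] - orig[k])))
  n_tr <- nrow(cand)
  tri <- list(i1 = integer(n_tr), i2 = integer(n_tr), s = numeric(n_tr),
              dx = numeric(n_tr), dy = numeric(n_tr), dz = numeric(n_tr))
  for (t in seq_len(n_tr)) {
    d1 <- cand[t, 1]; d2 <- cand[t, 2]
    o1 <- occm[d1, ]; o2 <- occm[d2, ]
    a <- which(o1 == 1L & o2 == 0L)  # spin orbital present only in bra
    b <- which(o2 == 1L & o1 == 0L)
    if (a %% 2L != b %% 2L) { tri$s[t] <- 0; next }
    sgn <- (-1)^(sum(o1[seq_len(a)]) + sum(o2[seq_len(b)]))
    p <- so_spatial(a); q <- so_spatial(b)
    tri$i1[t] <- d1; tri$i2[t] <- d2; tri$s[t] <- sgn
    tri$dx[t] <- dip[[1]][p, q]
    tri$dy[t] <- dip[[2]][p, q]
    tri$dz[t] <- dip[[3]][p, q]
  }
  keep <- tri$s != 0
  tri <- lapply(tri, `[`, keep)
  # diagonal (same-determinant) dipole expectation per determinant
  occ_sp <- occm[, seq(1, nso, 2), drop = FALSE] +
    occm[, seq(2, nso, 2), drop = FALSE]
  diag_dip <- sapply(1:3, function(k) occ_sp %*% diag(dip[[k]]))
  list(owner = owner, dcoef = dcoef, tri = tri, diag_dip = diag_dip)
}

# Electronic transition dipole (e * Angstrom) between CI states r1, r2.
#' @keywords internal
transition_dipole <- function(ctx, vectors, r1, r2) {
  w1 <- vectors[ctx$owner, r1] * ctx$dcoef
  w2 <- vectors[ctx$owner, r2] * ctx$dcoef
  tri <- ctx$tri
  ww <- tri$s * w1[tri$i1] * w2[tri$i2]
  wd <- w1 * w2
  -c(sum(ww * tri$dx) + sum(wd * ctx$diag_dip[, 1]),
     sum(ww * tri$dy) + sum(wd * ctx$diag_dip[, 2]),
     sum(ww * tri$dz) + sum(wd * ctx$diag_dip[, 3]))
}

#' Oscillator strength of a CI state
#'
#' Dipole-length form, `f_r = (2/3) dE |<S0|mu|Sr>|^2` in atomic units;
#' transition dipoles use the ZDO atom-condensed (point-charge)
#' approximation with the origin at the nuclear charge centroid.
#'
#' @param r excited-state index (1 = S1).
#' @param solution output of [solve_states()].
#' @param configs the configuration table the CI was built over.
#' @param scf the underlying `indo_scf` result.
#' @return non-negative numeric oscillator strength.
#' @export
oscillator_strength <- function(r, solution, configs, scf) {
  ctx <- tdm_context(configs, scf)
  mu <- transition_dipole(ctx, solution$vectors, 1L, r + 1L) *
    BOHR_PER_ANGSTROM
  de <- solution$excitation_energies_eV[r] / EV_PER_HARTREE
  (2 / 3) * de * sum(mu^2)
}

#' Compute an absorption stick spectrum
#'
#' Runs the full excited-state pipeline for one fragment: SCF under the
#' given point-charge environment, configuration enumeration, CI, and
#' oscillator strengths.
#'
#' @param fragment a `fragment_geometry` (typically a protonated bilin or
#'   a synthetic surrogate).
#' @param params an [indo_params()] set.
#' @param environment external point charges or `NULL` for vacuum.
#' @param n_singles,include_paired_doubles CI size controls (defaults from
#'   `params$ci`).
#' @param n_states number of excited states to report (default: all).
#' @param label environment label stored in the result.
#' @return an object of class `indo_spectrum`: a list with `states` (data
#'   frame: `state`, `energy_eV`, `wavelength_nm`, `oscillator_strength`),
#'   `n_configurations`, `ci_mode`, `environment_label`, the CI vectors of
#'   the reported states, and the `indo_scf` result.
#' @examples
#' frag <- make_toy_molecule("ethylene")
#' sp <- compute_spectrum(frag, indo_params(), n_singles = 8)
#' sp$states$wavelength_nm[1]
#' @export
compute_spectrum <- function(fragment, params = indo_params(),
                             environment = NULL, n_singles = NULL,
                             include_paired_doubles = NULL,
                             n_states = NULL, label = "vacuum") {
  if (is.null(n_singles)) n_singles <- params$ci$n_singles
  if (is.null(include_paired_doubles)) {
    include_paired_doubles <- params$ci$include_paired_doubles
  }
  scf <- scf_solve(fragment, params, environment)
  configs <- enumerate_configurations(scf, n_singles,
                                      include_paired_doubles)
  H <- build_ci_matrix(configs, scf)
  sol <- solve_states(H)
  nst <- length(sol$excitation_energies_eV)
  if (!is.null(n_states)) nst <- min(nst, n_states)
  ctx <- tdm_context(configs, scf)
  E <- sol$excitation_energies_eV[seq_len(nst)]
  f <- vapply(seq_len(nst), function(r) {
    mu <- transition_dipole(ctx, sol$vectors, 1L, r + 1L) *
      BOHR_PER_ANGSTROM
    (2 / 3) * (E[r] / EV_PER_HARTREE) * sum(mu^2)
  }, numeric(1))
  # deterministic ordering for degenerate states: energy, then index of
  # the largest-amplitude configuration
  amp <- apply(abs(sol$vectors[-1, 1 + seq_len(nst), drop = FALSE]), 2,
               which.max)
  ord <- order(round(E, 10), amp)
  states <- data.frame(state = seq_len(nst),
                       energy_eV = E[ord],
                       wavelength_nm = NM_EV / E[ord],
                       oscillator_strength = pmax(f[ord], 0))
  structure(list(states = states,
                 n_configurations = nrow(configs),
                 ci_mode = if (include_paired_doubles) {
                   "singles_plus_paired_doubles"
                 } else "singles_only",
                 environment_label = label,
                 ci_vectors = sol$vectors[, 1 + ord[seq_len(min(nst, 5))],
                                          drop = FALSE],
                 configs = configs,
                 ground_energy_eV = sol$ground_energy_eV,
                 scf = scf),
            class = "indo_spectrum")
}

#' @export
print.indo_spectrum <- function(x, n = 5, ...) {
  cat("<indo_spectrum> ", x$scf$fragment$label, " [",
      x$environment_label, "]\n", sep = "")
  cat("  CI:", x$n_configurations, "configurations (", x$ci_mode, ")\n")
  s1 <- x$states[1, ]
  cat(sprintf("  S0->S1: lambda1 = %.1f nm,  f1 = %.3f\n",
              s1$wavelength_nm, s1$oscillator_strength))
  print(utils::head(x$states, n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.indo_spectrum <- function(object, ...) {
  print(object, n = 10)
  invisible(object)
}

#' @export
plot.indo_spectrum <- function(x, n = NULL, xlim = NULL, ...) {
  s <- x$states
  if (!is.null(n)) s <- utils::head(s, n)
  if (is.null(xlim)) xlim <- rev(range(s$wavelength_nm))
  graphics::plot(NA, xlim = xlim,
                 ylim = c(0, max(s$oscillator_strength) * 1.1),
                 xlab = "wavelength (nm)", ylab = "oscillator strength",
                 main = paste0(x$scf$fragment$label, " [",
                               x$environment_label, "]"), ...)
  graphics::segments(s$wavelength_nm, 0, s$wavelength_nm,
                     s$oscillator_strength)
  invisible(x)
}

#' First-state summary of a spectrum
#'
#' @param spectrum an `indo_spectrum`.
#' @return named numeric vector with `lambda1_nm` and `f1`.
#' @export
lambda1 <- function(spectrum) {
  c(lambda1_nm = spectrum$states$wavelength_nm[1],
    f1 = spectrum$states$oscillator_strength[1])
}

#' Export a stick spectrum as TSV
#'
#' Writes columns `state`, `energy_eV`, `wavelength_nm`,
#' `oscillator_strength`, ordered by energy, after `#`-prefixed header
#' comments recording provenance.
#'
#' @param spectrum an `indo_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_spectrum <- function(spectrum, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write spectrum to ",
                                           path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    paste0("# phycospec stick spectrum: ",
           spectrum$scf$fragment$label),
    paste0("# environment: ", spectrum$environment_label,
           "; ci_mode: ", spectrum$ci_mode,
           "; n_configurations: ", spectrum$n_configurations)), con)
  utils::write.table(spectrum$states, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spectrum TSV written by [export_spectrum()]
#'
#' @param path file path.
#' @return data frame of states.
#' @export
read_spectrum <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
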