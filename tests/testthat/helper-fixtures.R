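# Shared fixtures, computed lazily once per test file.

# internal engine primitives exercised directly by the tests
sto_pair_overlap <- phycospec:::sto_pair_overlap
overlap_block <- phycospec:::overlap_block
rotation_about <- phycospec:::rotation_about
frag_coords <- phycospec:::frag_coords
gamma_two_center <- phycospec:::gamma_two_center

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_params <- function() fx("params", indo_params())

# tightly converged parameter set for oracle-level comparisons
fx_params_tight <- function() {
  fx("params_tight",
     indo_params(scf = list(convergence_energy_au = 1e-12,
                            convergence_density_rms = 1e-10,
                            max_iterations = 400, damping = 0.3,
                            diis = TRUE, diis_size = 8)))
}

# asymmetric 4-hydrogen cluster: smallest toy exercising every CI block
fx_h4 <- function() {
  fx("h4", fragment_geometry(
    data.frame(element = "H", name = paste0("H", 1:4),
               x = c(0, 0.9, 2.0, 2.9), y = c(0, 0, 0.5, 1.3),
               z = c(0, 0, 0, 0.2))))
}

fx_h4_scf <- function() fx("h4_scf", scf_solve(fx_h4(), fx_params_tight()))

fx_surrogate <- function() fx("surrogate", make_pcb_surrogate())

fx_surrogate_spectrum <- function() {
  fx("surrogate_spectrum",
     compute_spectrum(fx_surrogate()$fragment, fx_params(),
                      n_singles = 40, n_states = 10))
}
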