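# Default semi-empirical parameter set.
#
# Valence-only INDO parameterization: single-zeta Slater orbitals,
# CNDO/2-style core terms from orbital electronegativities, INDO one-center
# exchange (Slater-Condon G1/F2), Mataga-Nishimoto two-center repulsion,
# Wolfsberg-Helmholtz resonance integrals scaled by bond-type factors
# k_beta.  Energies in eV, Slater exponents in bohr^-1.
elements:
  "H":
    nshell: 1
    zeta: 1.20
    beta0: -9.0        # resonance parameter beta_A
    gamma: 12.848      # one-center Coulomb F0
    half_ia_s: 7.176   # (I+A)/2 for the valence s orbital
    half_ia_p: 0.0
    g1: 0.0            # one-center exchange integrals
    f2: 0.0
  "C":
    nshell: 2
    zeta: 1.625
    beta0: -21.0
    gamma: 11.11
    half_ia_s: 14.051
    half_ia_p: 5.572
    g1: 7.285
    f2: 4.727
  "N":
    nshell: 2
    zeta: 1.95
    beta0: -25.0
    gamma: 12.01
    half_ia_s: 19.316
    half_ia_p: 7.275
    g1: 9.416
    f2: 5.961
  "O":
    nshell: 2
    zeta: 2.275
    beta0: -31.0
    gamma: 13.00
    half_ia_s: 25.390
    half_ia_p: 9.111
    g1: 11.816
    f2: 7.250
  "S":
    nshell: 3
    zeta: 1.8167
    beta0: -18.15
    gamma: 10.09
    half_ia_s: 17.650
    half_ia_p: 6.989
    g1: 4.000
    f2: 3.000
# Bond-type scale factors for the Wolfsberg-Helmholtz resonance integral
# H_mu_nu = 0.5 * k_beta(A,B) * (beta_A + beta_B) * S_mu_nu.
k_beta:
  C-C: 1.10
  C-O: 1.10
  C-N: 0.70
  other: 1.20
# Two-center electron repulsion formula: mataga_nishimoto or ohno.
gamma_formula: mataga_nishimoto
scf:
  convergence_energy_au: 1.0e-8
  convergence_density_rms: 1.0e-6
  max_iterations: 200
  damping: 0.30          # fraction of the OLD density kept each step
  diis: true
  diis_size: 8
ci:
  n_singles: 169
  include_paired_doubles: true
# INDO/S-style channel weights applied to the p-p overlap used in the
# resonance integrals only (spectroscopic sigma/pi balance).
resonance_weights:
  sigma_pp: 1.267
  pi_pp: 0.585
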