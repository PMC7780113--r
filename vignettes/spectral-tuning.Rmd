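---
title: "Spectral tuning of bilin chromophores: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral tuning of bilin chromophores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycospec)
```

## The model

`phycospec` computes the S~0~→S~1~ absorption wavelength λ~1~ and
oscillator strength f~1~ of an open-chain tetrapyrrole (bilin)
chromophore, treated quantum-mechanically, inside a protein/solvent
environment treated as fixed point charges.  The electronic model has
three layers.

**Ground state.** A closed-shell SCF in the INDO approximation over a
valence-only Slater basis (H: 1s; C, N, O, S: ns + np).  The basis is
treated as orthonormal (zero differential overlap); the explicit
Slater-orbital overlap matrix enters only through the resonance
integrals, which take the Wolfsberg–Helmholtz form

$$H_{\mu\nu} = \tfrac12\, k_\beta(A,B)\,(\beta_A + \beta_B)\, S_{\mu\nu}$$

with bond-type scale factors $k_\beta$ defaulting to C–C = C–O = 1.10,
C–N = 0.70 and 1.20 for every other pair.  Two-electron integrals are
the Mataga–Nishimoto two-center $\gamma_{AB}$ (Ohno available as an
option) plus full one-center Coulomb/exchange structure from the
Slater–Condon parameters $F_0 = \gamma_{AA}$, $G_1$, $F_2$.  Core
diagonal terms follow the CNDO/2 electronegativity relation
$U_{\mu\mu} = -\tfrac12(I_\mu+A_\mu) - (Z_A - \tfrac12)\gamma_{AA}$.
The p–p overlaps used in the resonance integrals carry the
spectroscopic channel weights 1.267 (σ) / 0.585 (π) familiar from
INDO/S-style parameterizations; without them the dark σ→π* states of
small alkenes fall below the bright π→π* state.  The integral recipe
is an INDO/S-style parameterization assembled for this package:
every quantity above is data, editable in
`inst/extdata/indo_params.yaml` and through `indo_params()`, and
`scripts/calibrate_kbeta.R` re-anchors the $k_\beta$ table against a
measured band when a reference structure is available.  Absolute
wavelengths therefore carry parameterization uncertainty; *shifts*
between environments of the same chromophore, which are the scientific
output, are much more robust.

**Embedding.** Environment atoms enter as point charges $q_k$.  Each
basis function on atom A is shifted by
$-\sum_k q_k/|R_A - r_k|$ (atomic units, bare Coulomb at the ZDO
centers); the core–charge interaction is added to the scalar energy.
Only diagonal one-center terms are shifted — the simplest
ZDO-consistent choice; it makes the single-charge shift exactly
$-q/d$, which the test suite exploits as a closed-form oracle.

**Excited states.** CI over the SCF reference with the 169 lowest
singlet single excitations ψ(j,m), ranked by orbital-energy gap, plus
(by default) the paired double ψ(jj,mm) of each kept single — 338
configurations.  "Paired" means both electrons of ϕ~j~ promote to
ϕ~m~; general doubles ψ(kj,mn) are deliberately out of scope.  The
ground-state row couples to the paired doubles (through ⟨0|H|D⟩ =
(jm|jm)) and not to singles (Brillouin, enforced exactly).  Matrix
elements are evaluated in closed form; an independent
determinant-expansion engine (`build_ci_matrix(..., engine =
"determinant")`) implements the same CSF basis via Slater–Condon rules
and is held to a Jordan–Wigner Fock-space oracle in the tests, which
builds the many-electron Hamiltonian as an explicit matrix with no
reference to either production path.  Oscillator strengths use the
dipole-length form with ZDO atom-condensed transition densities; the
dipole origin is the nuclear charge centroid (immaterial in practice:
the transition density is traceless).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k_beta` | 1.10 / 0.70 / 1.20 | – | bond-type resonance scaling; dominant lever on absolute λ~1~ |
| `gamma_formula` | Mataga–Nishimoto | – | two-center repulsion; MN red-shifts π→π* relative to Ohno |
| `ci$n_singles` | 169 | – | CI truncation; E~1~ is variationally monotone in it |
| `ci$include_paired_doubles` | TRUE | – | paired doubles blue-shift λ~1~ (singles-only is ~5–15 % longer) |
| `scf$convergence_*` | 1e-8 au / 1e-6 rms | – | energy / density stopping criteria |
| water charges | −0.3307 / +0.1653 | e | fixed point charges per water O/H |
| environment radius R | 8 | Å | atom-wise closed-interval cutoff (min distance to any chromophore atom) |

The radius convention deserves a note: several cutoff conventions are
in circulation (minimum vs maximum atom distance, residue-wise vs
atom-wise inclusion); the package adopts the minimum-distance reading,
atom-wise, with a closed interval, and treats waters atom-wise too (a
water whose O alone is inside R contributes only its O charge).

## The charge pipeline

Protein charges come from the sliding capped-tripeptide protocol:
residues i−1, i, i+1 are cut out, the window's N terminus left as
–NH~2~, the C side capped as –COCH~3~ (methyl carbon at the removed
next residue's N position), the chain's true C terminus completed as
–COOH; hydrogens are placed by ideal-geometry rules (sp2 atoms planar,
sp3 tetrahedral; X–H 1.09/1.01/0.96/1.34 Å for C/N/O/S) rather than by
a semi-empirical optimization — a deliberate substitution, since the
downstream observable is dominated by heavy-atom geometry and net
charges.  Each window is solved with the same INDO SCF and ZDO
populations q~A~ = Z~A~ − Σ P~μμ~ are kept for the *central* residue
only.  A static per-residue template table
(`inst/extdata/residue_charge_template.tsv`, residual-corrected so
each residue sums exactly to its formal charge) serves as fast mode
and as fallback for non-convergent windows.  Ionizable side chains
default to standard states at pH 7 (Asp/Glu −1, Lys/Arg +1, His
neutral), configurable per residue.  Counter ions are abstract ±1 e
charges placed on a seeded 12–15 Å shell until the nearest integer to
the total charge is zero.

The chromophore QM region is cut at the cysteine thioether: the S–C
bond is severed and the chromophore carbon capped with a hydrogen link
atom at 1.09 Å along the former bond; the cysteine side chain beyond
the cap (SG and its hydrogen) is excluded from the charge environment.
The deposited heavy-atom geometry is used unrelaxed — only hydrogens
are added — and protonation of the central rings B and C is *imposed*
(the protonated form is the spectroscopically active one), never
predicted.

## What the synthetic generators emulate — and what they do not

`make_pcb_surrogate()` builds a planar methine-bridged bis-pyrrole: a
minimal conjugated system with the bilin's two central nitrogens (one
pyrrole-type N–H, one imine) and the same protonation semantics.  It
reproduces the *qualitative* physics — a bright π→π* S~1~ whose f~1~
collapses on deprotonation, red shift with conjugation length,
sensitivity to nearby charges — at desk scale (20 atoms, 54
electrons), but it is roughly half the conjugation length of
phycocyanobilin, so its λ~1~ (≈354 nm protonated, full CI) sits far
blue of the ~600 nm bilin bands.  `make_water_shell()` reproduces only
the statistical feature the embedding needs (a dense polar shell:
rigid TIP3P-geometry waters, O in [r~min~, r~max~] of the nearest
solute atom, O–O ≥ 2.6 Å, seeded rejection sampling), not real water
structure, orientation correlations, or dynamics.  Passing tests on
these generators therefore demonstrates the correctness of the
machinery — integrals, SCF, CI, embedding, selection logic — not
agreement with experiment on real phycobiliproteins, which
additionally requires the crystal structure, equilibrated waters, and
the calibration anchor.

## Numerical choices

* SCF: core-Hamiltonian diagonal guess; damped fixed point (default
  mixing 0.30 of the old density) with DIIS acceleration on the
  commutator FP−PF once two Fock matrices are banked; convergence at
  ΔE < 1e-8 au and RMS ΔP < 1e-6; deterministic throughout.
* Configuration ranking ties break by smaller virtual index, then
  larger occupied index; degenerate CI states order by energy, then by
  the index of their largest-amplitude configuration.
* The overlap engine evaluates Slater-orbital integrals analytically
  in prolate spheroidal coordinates (auxiliary A/B integrals, power
  series for B at small arguments) — exact to machine precision, as
  the quadrature-oracle tests confirm.
* Degenerate inputs: atoms closer than 0.5 Å to a point charge are
  dropped with a warning; empty environments are legal and equal
  vacuum; R = 0 always yields the vacuum row of a scan.
* Problem sizes used by the shipped tests and the acceptance script —
  full 338-configuration CI on the surrogate, 9-point radius scans,
  30-water shells, 5-residue peptides — were chosen as the smallest
  sizes that exercise every code path of the pipeline at full CI
  dimensionality.

## Design decisions on genuinely open points

* "338 lowest configurations" is read as 169 singles + their 169
  paired doubles; both knobs (`n_singles`,
  `include_paired_doubles`) are exposed so either reading can be run.
* Singlet-only CI: absorption from a closed-shell ground state;
  triplets are excluded.
* Dipole-length form for f~r~, the conventional choice with ZDO
  point-charge transition densities.
* One fixed candidate charge superset is filtered per radius in
  `radius_scan()`; water shells are not regenerated per R.
* `detect_convergence()` implements the literal reading of the
  settling criterion — the smallest scanned R whose next `window`
  successive λ~1~ steps all stay within `tol_nm` — so a flat *early*
  stretch (e.g. before any charge enters the cutoff) can satisfy it;
  inspect the scan rows when the environment is sparse.

## Known limitations

* No d orbitals, open shells, gradients, or general doubles; no
  polarizable or smeared charges; no pKa prediction; no
  crystallographic symmetry expansion (the oligomer chains must be
  present in the input file as deposited).
* Absolute λ~1~ inherits the re-parameterization uncertainty discussed
  above and should be read through the calibration step.
* The template charge mode is a coarse fallback; quantitative work
  should use the SCF charge engine.
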