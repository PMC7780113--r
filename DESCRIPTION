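Package: phycospec
Title: Semi-Empirical INDO-CI Absorption Spectra of Bilin Chromophores in
    Protein Electrostatic Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes S0->S1 absorption wavelengths and oscillator strengths
    of open-chain tetrapyrrole (bilin) chromophores such as phycocyanobilin
    with a self-contained semi-empirical INDO self-consistent-field engine,
    Wolfsberg-Helmholtz resonance integrals with bond-type scale factors,
    and configuration interaction over the lowest single excitations plus
    paired double excitations.  The protein and solvent environment enters
    as fixed point charges in the one-electron Hamiltonian; tools are
    provided to extract and chemically complete chromophores from PDB
    structures, derive residue point charges through a sliding capped
    tripeptide protocol, generate synthetic water and charge shells, scan
    the environment inclusion radius, and compare oligomeric environment
    models for a chromophore.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
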