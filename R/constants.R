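# Physical constants and element tables used across the package.
# Energies are carried in eV, coordinates in Angstroms; conversions to
# atomic units happen at the integral level.

#' @keywords internal
EV_PER_HARTREE <- 27.211386
#' @keywords internal
BOHR_PER_ANGSTROM <- 1.8897259886
#' @keywords internal
EV_ANGSTROM_COULOMB <- 14.399645  # e^2/(4 pi eps0), in eV * Angstrom
#' @keywords internal
NM_EV <- 1239.842  # lambda[nm] = NM_EV / E[eV]

# Covalent radii (Angstrom) for bond perception.
.covalent_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

# Standard valences for hydrogen completion; adjusted by formal charge
# (N+ -> 4, O- -> 1).
.standard_valence <- c(H = 1, C = 4, N = 3, O = 2, S = 2)

# X-H bond lengths (Angstrom) for rule-based hydrogen placement.
.xh_length <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

.atomic_number <- c(H = 1, C = 6, N = 7, O = 8, S = 16)

# Valence electron counts (core charge Z_A used by the ZDO electron-core
# and charge analysis terms).
.valence_electrons <- c(H = 1, C = 4, N = 5, O = 6, S = 6)

#' @keywords internal
element_supported <- function(el) el %in% names(.atomic_number)

#' @keywords internal
guess_element <- function(name) {
  # PDB atom name -> element when the element column is absent/blank.
  nm <- gsub("[0-9'*]", "", trimmed <- trimws(name))
  nm <- toupper(nm)
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "MG", "ZN", "NA"),
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         substr(nm, 1, 1))
}
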