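## Physical constants, centralized. Energies are kcal/mol everywhere inside
## the package; coordinates are Angstrom; temperatures Kelvin.

#' Physical constants used throughout the package
#'
#' A named list of the physical constants the package relies on:
#' \describe{
#'   \item{hartree_kcal}{1 Hartree in kcal/mol (627.5095).}
#'   \item{R_kcal}{Gas constant in kcal/(mol K) (1.98720425e-3).}
#'   \item{rotconst_mhz}{Conversion factor: B[MHz] = rotconst_mhz / I[amu A^2].}
#'   \item{cm1_kcal}{1 cm^-1 of photon energy in kcal/mol.}
#'   \item{bohr_angstrom}{1 Bohr in Angstrom.}
#' }
#'
#' @return Named list of constants.
#' @examples
#' phys_constants()$R_kcal * 298.15  # RT at room temperature, kcal/mol
#' @export
phys_constants <- function() {
  list(
    hartree_kcal  = 627.5095,
    R_kcal        = 1.98720425e-3,
    rotconst_mhz  = 505379.0,
    cm1_kcal      = 2.85914e-3,
    bohr_angstrom = 0.529177210903,
    # SI set used by the RRHO formulas
    h_SI    = 6.62607015e-34,   # J s
    kB_SI   = 1.380649e-23,     # J/K
    NA_SI   = 6.02214076e23,    # 1/mol
    c_cm    = 2.99792458e10,    # cm/s
    amu_kg  = 1.66053906660e-27,
    cal_J   = 4.184
  )
}

.const <- phys_constants()

## Standard atomic masses (amu), most abundant-isotope-weighted standard
## weights; enough coverage for organic host-guest chemistry plus noble gases.
.atomic_masses <- c(
  H = 1.008, D = 2.014, He = 4.002602,
  Li = 6.94, Be = 9.0121831, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403163, Ne = 20.1797, Na = 22.98976928, Mg = 24.305,
  Al = 26.9815385, Si = 28.085, P = 30.973761998, S = 32.06, Cl = 35.45,
  Ar = 39.948, K = 39.0983, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Br = 79.904, I = 126.90447, Xe = 131.293
)

#' Look up standard atomic masses
#'
#' @param symbols Character vector of element symbols (case-sensitive, e.g.
#'   `"Cl"`).
#' @return Numeric vector of masses in amu.
#' @examples
#' atomic_masses(c("C", "H", "H", "H"))
#' @export
atomic_masses <- function(symbols) {
  m <- .atomic_masses[symbols]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
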