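## Physical constants used throughout. Energies are stored in hartree
## internally; conversion to kcal/mol happens only at API boundaries.

#' Unit conversion and physical constants
#'
#' * `hartree_to_kcal`: 1 hartree in kcal/mol (CODATA).
#' * `gas_constant_kcal`: molar gas constant in kcal mol^-1 K^-1.
#' * `ev_nm`: hc in eV.nm, for wavelength <-> photon-energy conversion.
#'
#' @name constants
#' @keywords internal
NULL

hartree_to_kcal <- 627.509474
gas_constant_kcal <- 0.0019872041
ev_nm <- 1239.84198

#' Convert wavelength (nm) to photon energy (eV) and back
#'
#' The same expression E = hc/lambda serves both directions.
#'
#' @param x wavelength in nm, or energy in eV; must be positive.
#' @return the conjugate quantity.
#' @examples
#' nm_to_ev(330)
#' nm_to_ev(nm_to_ev(330))  # involution
#' @export
nm_to_ev <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  ev_nm / x
}

## Periodic-table symbols (elements 1-118), for coordinate validation.
element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

is_element_symbol <- function(x) x %in% element_symbols
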