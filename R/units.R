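#' Physical constants in the package unit system
#'
#' All public functions in kbff work in molecular-dynamics units: length in
#' nm, energy in kJ/mol, time in ps, charge in units of the elementary charge
#' e, temperature in K. SI conversions happen only at I/O boundaries (e.g.
#' conductivity in S/m, pressure in atm).
#'
#' @format A named list with elements
#' \describe{
#'   \item{kB}{Boltzmann constant times Avogadro's number, kJ/(mol K).}
#'   \item{f_coulomb}{Coulomb prefactor 1/(4 pi eps0), kJ nm/(mol e^2).}
#'   \item{NA_avogadro}{Avogadro's number, 1/mol.}
#'   \item{e_charge}{Elementary charge, C.}
#'   \item{kB_SI}{Boltzmann constant, J/K.}
#'   \item{atm_Pa}{Standard atmosphere, Pa.}
#' }
#' @export
kbff_constants <- list(
  kB          = 0.00831446261815324,   # kJ/(mol K)
  f_coulomb   = 138.935458,            # kJ nm / (mol e^2), = 1/(4 pi eps0)
  NA_avogadro = 6.02214076e23,
  e_charge    = 1.602176634e-19,       # C
  kB_SI       = 1.380649e-23,          # J/K
  atm_Pa      = 101325
)

#' Thermal energy k_B T
#'
#' @param temperature Temperature in K.
#' @return Thermal energy in kJ/mol.
#' @examples
#' thermal_energy(300) # ~2.494 kJ/mol
#' @export
thermal_energy <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  kbff_constants$kB * temperature
}

#' Convert a molar concentration to a number density
#'
#' @param conc_molar Concentration in mol/L.
#' @return Number density in 1/nm^3.
#' @export
molar_to_number_density <- function(conc_molar) {
  stopifnot(is.numeric(conc_molar), all(is.finite(conc_molar)))
  # mol/L * NA / (1e24 nm^3 per L)
  conc_molar * kbff_constants$NA_avogadro / 1e24
}

#' Convert a number density to a molar concentration
#'
#' @param n_per_nm3 Number density in 1/nm^3.
#' @return Concentration in mol/L.
#' @export
number_density_to_molar <- function(n_per_nm3) {
  stopifnot(is.numeric(n_per_nm3), all(is.finite(n_per_nm3)))
  n_per_nm3 * 1e24 / kbff_constants$NA_avogadro
}

#' Convert a pressure in atm to kJ/(mol nm^3)
#'
#' Used when comparing an external standard-state pressure with the ideal-gas
#' pressure k_B T n expressed in simulation units.
#'
#' @param p_atm Pressure in atm.
#' @return Pressure in kJ/(mol nm^3).
#' @export
atm_to_kjmolnm3 <- function(p_atm) {
  stopifnot(is.numeric(p_atm), all(is.finite(p_atm)))
  # 1 Pa = 1 J/m^3 -> * NA [1/mol] / 1000 [J/kJ] / 1e27 [nm^3/m^3]
  p_atm * kbff_constants$atm_Pa * kbff_constants$NA_avogadro / 1e30
}
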