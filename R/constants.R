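#' Physical constants used throughout the package
#'
#' Single source of truth for the unit system: lengths in angstrom, charges in
#' elementary charge units, energies in kcal/mol, temperatures in kelvin,
#' masses in amu, times in ps.
#'
#' @return A named list with components:
#' \describe{
#'   \item{k_coulomb}{Coulomb constant, 332.0636 kcal*A/(mol*e^2) (AMBER
#'     convention, so canonical-GB cross checks are meaningful).}
#'   \item{k_boltzmann}{Boltzmann constant, 0.0019872 kcal/(mol*K).}
#'   \item{conc_factor}{Concentration conversion, 6.02e-4 particles per
#'     cubic angstrom for a 1 mol/L solution.}
#'   \item{eps_out_default}{Default solvent dielectric constant, 78.5.}
#'   \item{akma}{Energy-to-kinetic conversion, 418.4 amu*A^2/ps^2 per
#'     kcal/mol.}
#' }
#' @examples
#' gbion_constants()$conc_factor  # 6.02e-4
#' @export
gbion_constants <- function() {
  list(
    k_coulomb       = 332.0636,
    k_boltzmann     = 0.0019872,
    conc_factor     = 6.02e-4,
    eps_out_default = 78.5,
    akma            = 418.4
  )
}

#' Bjerrum length of a dielectric solvent
#'
#' Distance at which two unit charges interact with thermal energy k_B*T;
#' about 7.1 A in water at 300 K with the package's constants.
#'
#' @param temperature temperature in K.
#' @param eps_out solvent dielectric constant.
#' @return Bjerrum length in angstrom.
#' @examples
#' bjerrum_length()  # ~7.1
#' @export
bjerrum_length <- function(temperature = 300, eps_out = 78.5) {
  cst <- gbion_constants()
  cst$k_coulomb / (eps_out * cst$k_boltzmann * temperature)
}
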