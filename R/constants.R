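## Internal unit system: kcal/mol, Angstrom, radian, amu, ps, Kelvin.

#' Physical constants used throughout the package
#'
#' Boltzmann constant in kcal/(mol K), the electrostatic conversion factor
#' in kcal Angstrom/(mol e^2), the conversion from kcal/mol to the
#' amu Angstrom^2/ps^2 energy unit used by the Langevin integrator, and the
#' standard-state volume (1 M) in cubic Angstrom.
#'
#' @format Named numeric vector.
#' @export
fm_constants <- c(
  kB          = 0.0019872041,
  coulomb     = 332.0637128,
  kcal_akma   = 418.4,
  v_standard  = 1660.5392
)

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol.
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  fm_constants[["kB"]] * temperature
}
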