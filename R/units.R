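#' Physical constants and unit system
#'
#' The package works throughout in the MD-native unit system: length in
#' angstroms (\eqn{\text{\AA}}), time in femtoseconds, mass in atomic mass
#' units (amu), energy in kcal/mol and temperature in kelvin.  Two constants
#' tie these together:
#'
#' * `kB`: Boltzmann constant, 0.0019872041 kcal/(mol K).
#' * `energy_to_internal`: conversion from kcal/mol to the internal
#'   kinetic-energy unit amu A^2/fs^2, equal to 4.184e-4.  Accelerations are
#'   computed as `force * energy_to_internal / mass` so the conversion is
#'   applied exactly once.
#'
#' @format A list with elements `kB` and `energy_to_internal`.
#' @examples
#' md_units$kB * 300   # thermal energy at 300 K in kcal/mol
#' @export
md_units <- list(
  kB = 0.0019872041,          # kcal/(mol K)
  energy_to_internal = 4.184e-4  # kcal/mol -> amu A^2/fs^2
)

#' Instantaneous kinetic temperature of a velocity set
#'
#' @param velocities n x 3 matrix of velocities in A/fs.
#' @param masses length-n vector of masses in amu.
#' @param ndof number of kinetic degrees of freedom; defaults to `3 n`.
#'   Pass `3 n - 3` when centre-of-mass momentum is constrained.
#' @return Temperature in kelvin.
#' @export
kinetic_temperature <- function(velocities, masses, ndof = 3L * length(masses)) {
  ke <- 0.5 * sum(masses * rowSums(velocities^2)) / md_units$energy_to_internal
  2 * ke / (ndof * md_units$kB)
}
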