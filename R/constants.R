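# Physical constants used throughout; pinned values so results are stable
# across R versions.
.const <- list(
  eps0       = 8.8541878128e-12, # vacuum permittivity, F/m
  debye      = 3.33564e-30,      # 1 debye in C*m
  e_ang_to_D = 4.80320,          # 1 elementary charge * angstrom in debye
  kB         = 1.380649e-23,     # Boltzmann constant, J/K
  e_charge   = 1.602176634e-19   # elementary charge, C
)

#' Thermal energy at a given temperature
#'
#' Convenience for `k_B * T`, the default interaction-energy threshold of
#' [debye_cutoff()].
#'
#' @param temperature_K Temperature in kelvin (default 297 K, the simulation
#'   and measurement temperature of the avidin study conditions emulated by
#'   the synthetic generators).
#' @return Energy in joules.
#' @export
#' @examples
#' thermal_energy(297)
thermal_energy <- function(temperature_K = 297) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  .const$kB * temperature_K
}
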