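#' Physical constants used throughout the package
#'
#' CODATA values for the elementary charge and the unified atomic mass unit.
#' All internal computations are in SI units (m, V, T, s, rad/s).
#'
#' @return Named list with `elementary_charge` (C) and `atomic_mass_unit` (kg).
#' @export
#' @examples
#' icr_constants()$elementary_charge
icr_constants <- function() {
  list(
    elementary_charge = 1.602176634e-19,  # C, exact (SI 2019)
    atomic_mass_unit  = 1.66053906660e-27 # kg, CODATA 2018
  )
}

.const <- list(
  e = 1.602176634e-19,
  u = 1.66053906660e-27
)
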