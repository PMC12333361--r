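#' Physical constants used by the geminate polarization probability
#'
#' CODATA values of the Bohr magneton over the reduced Planck constant,
#' and the conversion from MHz to angular frequency. These are fixed;
#' the function exists so that every consumer uses the same values.
#'
#' @return A list with elements `mu_B_over_hbar` (rad s^-1 T^-1) and
#'   `mhz_to_rad_s` (rad s^-1 per MHz).
#' @examples
#' physical_constants()$mu_B_over_hbar
#' @export
physical_constants <- function() {
  # mu_B = 9.2740100783e-24 J/T, hbar = 1.054571817e-34 J s (CODATA 2018)
  list(
    mu_B_over_hbar = 9.2740100783e-24 / 1.054571817e-34,
    mhz_to_rad_s = 2 * pi * 1e6
  )
}
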