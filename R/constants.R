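# Boltzmann constant in pN nm / K
.kB_pN_nm <- 0.0138065

#' Thermal energy in piconewton-nanometers
#'
#' Experiments are performed at 22 degrees Celsius unless stated otherwise,
#' giving \eqn{k_B T \approx 4.075} pN nm.
#'
#' @param temp_c Temperature in degrees Celsius (default 22).
#' @return Thermal energy \eqn{k_B T} in pN nm.
#' @examples
#' thermal_energy()      # ~4.075 pN nm at 22 C
#' thermal_energy(37)
#' @export
thermal_energy <- function(temp_c = 22) {
  stopifnot(is.numeric(temp_c), temp_c > -273.15)
  .kB_pN_nm * (temp_c + 273.15)
}

#' Coarse-grained simulation unit registry
#'
#' Conversion factors for the reduced units used by coarse-grained DNA
#' simulations whose outputs this package ingests: length unit 0.8518 nm,
#' energy unit 41.42 pN nm (so 0.1 energy units is about 1 kBT at 22 C, the
#' hydrogen-bond calling threshold), and the derived force and spring
#' stiffness units.
#'
#' @return Named list: `length_nm`, `energy_pN_nm`, `force_pN`,
#'   `stiffness_pN_per_nm`.
#' @export
sim_units <- function() {
  len <- 0.8518
  en <- 41.42
  list(length_nm = len, energy_pN_nm = en, force_pN = en / len,
       stiffness_pN_per_nm = en / len^2)
}

#' Default polymer parameters
#'
#' Package-wide defaults for the elastic description of ssDNA and dsDNA:
#' ssDNA contour length 0.68 nm per nucleotide with persistence length
#' 1.04 nm, dsDNA helical rise 0.34 nm per base pair with persistence length
#' 50 nm. With these values the Marko-Siggia extensions of ssDNA and dsDNA
#' cross near 4.25 pN and the finite-chain (short-chain) ssDNA formula moves
#' the crossover to about 1.8 pN, consistent with the bow assay calibration.
#' All are overridable wherever they are consumed.
#'
#' @return Named list: `ssdna_nm_per_nt`, `ssdna_persistence_nm`,
#'   `dsdna_rise_nm`, `dsdna_persistence_nm`, `temp_c`.
#' @export
polymer_defaults <- function() {
  list(
    ssdna_nm_per_nt      = 0.68,
    ssdna_persistence_nm = 1.04,
    dsdna_rise_nm        = 0.34,
    dsdna_persistence_nm = 50,
    temp_c               = 22
  )
}
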