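#' Physical constants and unit conversions
#'
#' The internal unit system is eV (energy), nm (length), ps (time) and the
#' derived mass unit eV ps^2 nm^-2 (= 96.485 a.m.u.).  Temperatures are in
#' kelvin, charges in units of the elementary charge e, stresses in MPa.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, eV K^-1.}
#'   \item{kC}{Coulomb constant e^2/(4 pi eps0), eV nm e^-2.}
#'   \item{amu}{One a.m.u. in internal mass units (eV ps^2 nm^-2).}
#'   \item{mpa_per_evnm3}{1 eV nm^-3 expressed in MPa.}
#'   \item{evnm2_per_Nm}{1 N m^-1 expressed in eV nm^-2.}
#'   \item{nmps_per_ms}{1 m s^-1 expressed in nm ps^-1.}
#' }
#' @export
zw_units <- list(
  kB             = 8.617333262e-5,   # eV/K
  kC             = 1.4400,           # eV nm / e^2
  amu            = 1 / 96.48533212,  # internal mass units per a.m.u.
  mpa_per_evnm3  = 160.2176634,      # 1 eV/nm^3 in MPa
  evnm2_per_Nm   = 6.241509074,      # 1 N/m in eV/nm^2
  nmps_per_ms    = 1e-3              # 1 m/s in nm/ps
)

#' Thermal energy
#'
#' @param T_K temperature in kelvin.
#' @return `k_B T` in meV.
#' @examples
#' thermal_energy(1000)  # ~ 86 meV
#' @export
thermal_energy <- function(T_K) {
  stopifnot(all(T_K >= 0))
  zw_units$kB * T_K * 1e3
}

#' Coulomb energy gain of a hooked cation
#'
#' Electrostatic estimate of the strength of a transient interlayer bond:
#' the difference in Coulomb attraction of a cation sitting midway between
#' two adjacent anions of the opposing layer (separation `r_hook` from each)
#' and the same cation in its flat-layer configuration (separation `r_flat`).
#'
#' @param q charge magnitude in units of e.
#' @param r_hook cation--anion distance in the hooked configuration, nm.
#' @param r_flat cation--anion distance in the flat configuration, nm.
#' @return Energy difference `2 k_C q^2 (1/r_hook - 1/r_flat)` in meV.
#' @examples
#' transient_bond_energy(0.25, 0.41, 0.51)  # ~ 85 meV
#' @export
transient_bond_energy <- function(q, r_hook, r_flat) {
  stopifnot(q >= 0, r_hook > 0, r_flat > 0)
  2 * zw_units$kC * q^2 * (1 / r_hook - 1 / r_flat) * 1e3
}
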