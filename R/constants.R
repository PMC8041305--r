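# Physical constants and unit-bridge factors. Centralised so every B22 / density
# conversion in the package is bit-identical.

.const <- list(
  avogadro      = 6.02214076e23,  # mol^-1 (exact, SI 2019)
  boltzmann_J_K = 1.380649e-23,   # J K^-1 (exact, SI 2019)
  nm3_per_L     = 1e24,           # 1 L = 1e24 nm^3
  mL_per_nm3    = 1e-21,          # 1 nm^3 = 1e-21 mL
  close_packing = 0.7404805,      # pi/(3*sqrt(2)), FCC packing fraction limit
  # dynamic viscosity of water, mPa s (Huber et al. reference correlation)
  water_viscosity_mPas = c("278.15" = 1.5182, "298.15" = 0.8900),
  # HEWL extinction coefficient at 280 nm, mL mg^-1 cm^-1
  hewl_extinction_280 = 2.64
)

#' Convert a mass concentration to a number density
#'
#' Bridges the experimental concentration axis (mg/mL) to the number density
#' used by the thermodynamic model (molecules per nm^3),
#' `rho = gamma * N_A / molar_mass / 1e24`.
#'
#' @param gamma Mass concentration in mg/mL (equivalently g/L). Vectorised.
#' @param molar_mass Molar mass in g/mol.
#' @return Number density in nm^-3.
#' @seealso [mass_concentration()] for the exact inverse.
#' @examples
#' number_density(90, 14300)
#' @export
number_density <- function(gamma, molar_mass) {
  stopifnot(is.numeric(gamma), is.numeric(molar_mass))
  if (any(gamma < 0)) stop("`gamma` must be non-negative (mg/mL)")
  if (any(molar_mass <= 0)) stop("`molar_mass` must be positive (g/mol)")
  gamma / molar_mass * .const$avogadro / .const$nm3_per_L
}

#' Convert a number density to a mass concentration
#'
#' Exact inverse of [number_density()].
#'
#' @param rho Number density in nm^-3. Vectorised.
#' @param molar_mass Molar mass in g/mol.
#' @return Mass concentration in mg/mL.
#' @export
mass_concentration <- function(rho, molar_mass) {
  stopifnot(is.numeric(rho), is.numeric(molar_mass))
  if (any(rho < 0)) stop("`rho` must be non-negative (nm^-3)")
  if (any(molar_mass <= 0)) stop("`molar_mass` must be positive (g/mol)")
  rho * molar_mass / .const$avogadro * .const$nm3_per_L
}

#' Protein concentration from UV absorbance
#'
#' Beer-Lambert reduction of a 280 nm absorbance reading using the lysozyme
#' extinction coefficient 2.64 mL mg^-1 cm^-1.
#'
#' @param a280 Absorbance at 280 nm (dimensionless). Vectorised.
#' @param path_cm Optical path length in cm (default 1).
#' @param extinction Extinction coefficient in mL mg^-1 cm^-1.
#' @return Concentration in mg/mL.
#' @export
concentration_from_absorbance <- function(a280, path_cm = 1,
                                          extinction = .const$hewl_extinction_280) {
  if (any(a280 < 0)) stop("`a280` must be non-negative")
  if (any(path_cm <= 0)) stop("`path_cm` must be positive")
  a280 / (extinction * path_cm)
}
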