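# Physical constants (CODATA) and small solvent-property helpers.
# Internal units throughout the package: nm, ns, kJ/mol, elementary charges e.

.KB <- 8.31446261815324e-3   # kJ mol^-1 K^-1
.KE <- 138.935458            # Coulomb prefactor, kJ mol^-1 nm e^-2 (vacuum)
.NA_AVOGADRO <- 6.02214076e23
.E_CHARGE <- 1.602176634e-19 # C
.EPS0 <- 8.8541878128e-12    # F/m
.KB_J <- 1.380649e-23        # J/K

# nm^3/ns -> M^-1 s^-1 for a bimolecular rate constant
.RATE_NM3NS_TO_MS <- .NA_AVOGADRO * 1e-24 * 1e9

#' Thermal energy
#'
#' @param temperature temperature in K.
#' @return kT in kJ/mol.
#' @export
kT <- function(temperature = 298.15) .KB * temperature

#' Viscosity of water
#'
#' Vogel equation fit for liquid water, accurate to about 1% between 0 and
#' 100 degrees C.
#'
#' @param temperature temperature in K.
#' @return dynamic viscosity in Pa s.
#' @export
water_viscosity <- function(temperature = 298.15) {
  2.414e-5 * 10^(247.8 / (temperature - 140))
}

#' Relative permittivity of water
#'
#' Malmberg-Maryott polynomial in degrees Celsius.
#'
#' @param temperature temperature in K.
#' @return dimensionless relative permittivity.
#' @export
water_permittivity <- function(temperature = 298.15) {
  t <- temperature - 273.15
  87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
}

#' Stokes-Einstein diffusion coefficients
#'
#' Translational and rotational diffusion coefficients of a sphere.
#'
#' @param radius hydrodynamic radius in nm.
#' @param temperature temperature in K.
#' @param viscosity dynamic viscosity in Pa s.
#' @return list with `Dt` (nm^2/ns) and `Dr` (rad^2/ns).
#' @export
stokes_einstein <- function(radius, temperature = 298.15,
                            viscosity = water_viscosity(temperature)) {
  stopifnot(radius > 0, temperature > 0, viscosity > 0)
  r_m <- radius * 1e-9
  dt <- .KB_J * temperature / (6 * pi * viscosity * r_m)   # m^2/s
  dr <- .KB_J * temperature / (8 * pi * viscosity * r_m^3) # 1/s
  list(Dt = dt * 1e9, Dr = dr * 1e-9)  # nm^2/ns, rad^2/ns
}

#' Rod diffusion coefficients
#'
#' Translational (orientation-averaged) and end-over-end rotational diffusion
#' of a rigid rod (Tirado-Garcia de la Torre with simple end corrections),
#' used for rigid DNA fragments.
#'
#' @param length rod length in nm.
#' @param diameter rod diameter in nm.
#' @param temperature temperature in K.
#' @param viscosity dynamic viscosity in Pa s.
#' @return list with `Dt` (nm^2/ns) and `Dr` (rad^2/ns).
#' @export
rod_diffusion <- function(length, diameter = 2.0, temperature = 298.15,
                          viscosity = water_viscosity(temperature)) {
  stopifnot(length > diameter)
  p <- length / diameter
  l_m <- length * 1e-9
  kbt <- .KB_J * temperature
  dt <- kbt * (log(p) + 0.312) / (3 * pi * viscosity * l_m)
  dr <- 3 * kbt * (log(p) - 0.662) / (pi * viscosity * l_m^3)
  list(Dt = dt * 1e9, Dr = dr * 1e-9)
}
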