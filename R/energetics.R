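# Screened electrostatics, excluded volume, and DNA step elasticity.

#' Debye screening length
#'
#' Debye length of a symmetric electrolyte from the standard ionic-strength
#' formula kappa^2 = 2 N_A e^2 I / (eps0 eps_r kB T).
#'
#' @param ionic_strength ionic strength in mol/L. `0` returns `Inf`.
#' @param temperature temperature in K.
#' @param epsr relative permittivity of the solvent.
#' @return Debye length kappa^-1 in nm.
#' @examples
#' debye_length(0.15)  # ~0.79 nm in water at room temperature
#' @export
debye_length <- function(ionic_strength, temperature = 298.15, epsr = 78.5) {
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (ionic_strength == 0) return(Inf)
  kappa2 <- 2 * .NA_AVOGADRO * .E_CHARGE^2 * (ionic_strength * 1e3) /
    (.EPS0 * epsr * .KB_J * temperature)            # m^-2
  1e9 / sqrt(kappa2)
}

#' Electrostatic / nonbonded parameter set
#'
#' Bundles the parameters of the screened-Coulomb (Debye-Hueckel) plus
#' short-range (WCA soft-sphere) nonbonded model.  The electrostatic term is
#' truncated at `cutoff_factor` Debye lengths and shifted to zero there, so
#' truncation error stays below thermal noise.
#'
#' @param ionic_strength ionic strength, mol/L.
#' @param temperature temperature, K.
#' @param epsr relative permittivity.
#' @param wca_eps energy scale of the short-range repulsion, kJ/mol.
#' @param cutoff_factor electrostatic cutoff in units of the Debye length.
#' @return object of class `elec_params`.
#' @export
elec_params <- function(ionic_strength = 0.15, temperature = 298.15,
                        epsr = 78.5, wca_eps = 1.0, cutoff_factor = 5) {
  ld <- debye_length(ionic_strength, temperature, epsr)
  kappa <- if (is.finite(ld)) 1 / ld else 0
  rc <- if (kappa > 0) cutoff_factor / kappa else 1e6
  structure(list(
    ionic_strength = ionic_strength,
    temperature = temperature,
    epsr = epsr,
    debye_length = ld,
    kappa = kappa,
    coulomb_prefactor = .KE / epsr,
    cutoff = rc,
    wca_eps = wca_eps,
    kT = kT(temperature),
    beta = 1 / kT(temperature)
  ), class = "elec_params")
}

#' @export
print.elec_params <- function(x, ...) {
  cat(sprintf("Debye-Hueckel parameters: I = %g M, T = %g K, eps_r = %g\n",
              x$ionic_strength, x$temperature, x$epsr))
  cat(sprintf("  Debye length %.3f nm, cutoff %.2f nm, WCA eps %g kJ/mol\n",
              x$debye_length, x$cutoff, x$wca_eps))
  invisible(x)
}

#' Screened Coulomb pair energy
#'
#' Debye-Hueckel interaction of two point charges (point-charge form, no
#' ion-size denominator): E = ke q1 q2 exp(-kappa r) / (eps_r r).
#'
#' @param q1,q2 charges in e.
#' @param r separation in nm, > 0.
#' @param params an [elec_params()] object.
#' @return energy in kJ/mol.
#' @examples
#' dh_pair_energy(1, 1, 1, elec_params(ionic_strength = 0))  # ~1.77 kJ/mol
#' @export
dh_pair_energy <- function(q1, q2, r, params = elec_params()) {
  if (any(r <= 0)) stop("r must be > 0")
  params$coulomb_prefactor * q1 * q2 * exp(-params$kappa * r) / r
}

#' Interaction energy between two CG structures
#'
#' Pairwise sum over inter-structure bead pairs, decomposed into the screened
#' Coulomb part (cutoff-shifted Debye-Hueckel between charged beads) and the
#' short-range part (WCA soft-sphere repulsion, zero beyond bead contact).
#'
#' @param a,b `cg_structure` objects (or bead data frames with columns
#'   x, y, z, radius, charge).
#' @param params an [elec_params()] object.
#' @return object of class `energy_decomposition`: list with `coulomb`,
#'   `short_range`, `total` (kJ/mol) and `min_surface_dist` (nm).
#' @export
interaction_energy <- function(a, b, params = elec_params()) {
  ba <- bead_matrix(a)
  bb <- bead_matrix(b)
  res <- cpp_interaction_energy(ba$xyz, ba$radius, ba$charge,
                                bb$xyz, bb$radius, bb$charge,
                                params$coulomb_prefactor, params$kappa,
                                params$cutoff, params$wca_eps)
  structure(res, class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("Interaction energy: total %.4g kJ/mol (Coulomb %.4g, short-range %.4g)\n",
              x$total, x$coulomb, x$short_range))
  invisible(x)
}

# extract coordinates/radii/charges from a cg_structure or bead data frame
bead_matrix <- function(x) {
  b <- if (inherits(x, "cg_structure")) x$beads else as.data.frame(x)
  list(xyz = as.matrix(b[, c("x", "y", "z")]),
       radius = b$radius, charge = b$charge)
}

#' Base-pair step elastic parameters
#'
#' Parameters of the rigid base-pair DNA model: rest step (tilt, roll, twist
#' in degrees; shift, slide, rise in nm) and a 6x6 symmetric positive-definite
#' stiffness matrix (kJ/mol per degree^2 or nm^2).  By default the bending
#' stiffness (tilt/roll) is set analytically so that the chain's bending
#' persistence length matches `persistence_length` (Lp = k h / kT per step of
#' rise h), and the twist stiffness corresponds to a torsional persistence
#' length of 100 nm.
#'
#' @param persistence_length target bending persistence length, nm.
#' @param twist rest twist per step, degrees.
#' @param rise rest rise per step, nm.
#' @param torsional_persistence torsional persistence length, nm.
#' @param k_displacement stiffness of shift/slide/rise, kJ/mol/nm^2.
#' @param temperature temperature used in the Lp calibration, K.
#' @param stiffness optional full 6x6 stiffness matrix overriding the
#'   defaults (order: tilt, roll, twist, shift, slide, rise).
#' @return object of class `bp_step_params`.
#' @export
bp_step_params <- function(persistence_length = 50, twist = 36, rise = 0.334,
                           torsional_persistence = 100,
                           k_displacement = 2000,
                           temperature = 310.15, stiffness = NULL) {
  if (rise < 0.3 || rise > 0.38) stop("rest rise should be ~0.33-0.34 nm")
  if (twist < 30 || twist > 40) stop("rest twist should be ~34-36 degrees")
  deg2 <- (pi / 180)^2
  if (is.null(stiffness)) {
    kbend <- persistence_length * kT(temperature) / rise * deg2    # kJ/mol/deg^2
    ktw <- torsional_persistence * kT(temperature) / rise * deg2
    stiffness <- diag(c(kbend, kbend, ktw,
                        k_displacement, k_displacement, k_displacement))
  }
  stiffness <- as.matrix(stiffness)
  if (!isTRUE(all.equal(stiffness, t(stiffness))) ||
      any(eigen(stiffness, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("stiffness must be symmetric positive-definite")
  dimnames(stiffness) <- list(
    c("tilt", "roll", "twist", "shift", "slide", "rise"),
    c("tilt", "roll", "twist", "shift", "slide", "rise"))
  structure(list(
    rest_step = c(tilt = 0, roll = 0, twist = twist,
                  shift = 0, slide = 0, rise = rise),
    stiffness = stiffness,
    persistence_length_target = persistence_length
  ), class = "bp_step_params")
}

#' @export
print.bp_step_params <- function(x, ...) {
  cat(sprintf("Rigid base-pair step: twist %g deg, rise %g nm, Lp target %g nm\n",
              x$rest_step["twist"], x$rest_step["rise"],
              x$persistence_length_target))
  invisible(x)
}

# engine representation: diagonal stiffness in rad/nm units + rest twist (rad)
step_params_engine <- function(params) {
  K <- params$stiffness
  rad2 <- (180 / pi)^2
  list(k6 = c(K[1, 1] * rad2, K[2, 2] * rad2, K[3, 3] * rad2,
              K[4, 4], K[5, 5], K[6, 6]),
       twist0 = params$rest_step[["twist"]] * pi / 180,
       rise0 = params$rest_step[["rise"]])
}

#' Base-pair step coordinates of a CG DNA conformation
#'
#' Computes the six step coordinates between consecutive base-pair frames:
#' the displacement of the next frame origin expressed in the current frame
#' (shift, slide, rise) and the rotation-vector components of the relative
#' rotation (tilt, roll, twist), the same parameterization the dynamics
#' engine uses.
#'
#' @param x a DNA `cg_structure` (with base-pair rigid bodies).
#' @return matrix with one row per step and columns tilt, roll, twist
#'   (degrees), shift, slide, rise (nm).
#' @export
bp_step_coords <- function(x) {
  stopifnot(inherits(x, "cg_structure"))
  bodies <- x$bodies
  if (is.null(bodies)) stop("structure has no rigid base-pair bodies")
  n <- nrow(bodies$origin)
  if (n < 2) return(matrix(numeric(0), 0, 6))
  out <- matrix(0, n - 1, 6)
  colnames(out) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  for (i in seq_len(n - 1)) {
    R1 <- matrix(bodies$R[i, ], 3, 3, byrow = TRUE)
    R2 <- matrix(bodies$R[i + 1, ], 3, 3, byrow = TRUE)
    u <- bodies$origin[i + 1, ] - bodies$origin[i, ]
    v <- drop(t(R1) %*% u)
    phi <- rot_log_R(t(R1) %*% R2)
    out[i, ] <- c(phi * 180 / pi, v)
  }
  out
}

# rotation-vector (log map) of a rotation matrix
rot_log_R <- function(Q) {
  tr <- sum(diag(Q))
  cth <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(cth)
  ax <- c(Q[3, 2] - Q[2, 3], Q[1, 3] - Q[3, 1], Q[2, 1] - Q[1, 2])
  if (th < 1e-7) return(ax / 2)
  th / (2 * sin(th)) * ax
}

#' Internal elastic energy of a DNA conformation
#'
#' Sum over base-pair steps of the quadratic form (1/2) x' K x, where x is
#' the deviation of the six step coordinates from their rest values.
#'
#' @param x either a DNA `cg_structure`, or a numeric matrix of per-step
#'   deviations from rest (columns tilt, roll, twist in degrees; shift,
#'   slide, rise in nm).
#' @param params a [bp_step_params()] object.
#' @return energy in kJ/mol.
#' @export
dna_internal_energy <- function(x, params = bp_step_params()) {
  if (inherits(x, "cg_structure")) {
    dev <- bp_step_coords(x)
    dev <- sweep(dev, 2, params$rest_step)
  } else {
    dev <- as.matrix(x)
    if (ncol(dev) != 6) stop("step deviations must have 6 columns")
  }
  K <- params$stiffness
  0.5 * sum(vapply(seq_len(nrow(dev)),
                   function(i) drop(dev[i, ] %*% K %*% dev[i, ]),
                   numeric(1)))
}
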