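# Overdamped Langevin (Brownian) dynamics of CG systems, association
# campaigns and first-contact detection.

#' Simulation configuration
#'
#' @param n_steps number of integration steps.
#' @param dt time step, ns.
#' @param save_stride save a frame every `save_stride` steps.
#' @param temperature temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @param seed integer RNG seed (recorded in all outputs).
#' @param confine_radius radius of a reflecting confinement sphere centred at
#'   the origin, nm (`NA` for none).
#' @param contact_cutoff inter-molecular surface-to-surface contact
#'   criterion, nm.
#' @param stop_on_contact stop the run at the first inter-molecular contact.
#' @param rigid named or unnamed logical vector: treat each molecule as a
#'   single rigid body?  Default: proteins rigid, DNA flexible (rigid
#'   base-pair chain), generic bead systems free.
#' @param hydro_radius named list overriding hydrodynamic radii (nm):
#'   `protein` (default 2.0), `bp` (rigid base-pair unit, default 1.0),
#'   `dna_rod_diameter` (rigid DNA, default 2.0).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 1e5, dt = 1e-3, save_stride = 1000,
                       temperature = 310.15,
                       viscosity = water_viscosity(temperature),
                       seed = 1, confine_radius = NA,
                       contact_cutoff = 0.6, stop_on_contact = FALSE,
                       rigid = NULL, hydro_radius = list()) {
  stopifnot(dt > 0, n_steps >= 1, save_stride >= 1, temperature > 0)
  hr <- list(protein = 2.0, bp = 1.0, dna_rod_diameter = 2.0)
  hr[names(hydro_radius)] <- hydro_radius
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 save_stride = as.integer(save_stride),
                 temperature = temperature, viscosity = viscosity,
                 seed = as.integer(seed), confine_radius = confine_radius,
                 contact_cutoff = contact_cutoff,
                 stop_on_contact = stop_on_contact, rigid = rigid,
                 hydro_radius = hr),
            class = "sim_config")
}

# assemble the flat arrays the engine consumes from 1-2 structures
assemble_system <- function(structures, config) {
  if (inherits(structures, "cg_structure")) structures <- list(structures)
  nmol <- length(structures)
  rigid <- config$rigid
  if (is.null(rigid)) {
    rigid <- vapply(structures, function(s) s$molecule == "protein", logical(1))
  }
  rigid <- rep_len(rigid, nmol)
  hr <- config$hydro_radius
  se_bp <- stokes_einstein(hr$bp, config$temperature, config$viscosity)

  beads <- list(); springs <- list(); steps <- list()
  body_o <- list(); body_R <- list()
  bodyDt <- numeric(0); bodyDr <- numeric(0)
  bead_body <- integer(0); mol_id <- integer(0); beadD <- numeric(0)
  step_par <- NULL
  nbead <- 0L; nbody <- 0L
  for (m in seq_len(nmol)) {
    s <- structures[[m]]
    b <- s$beads
    n <- nrow(b)
    xyz <- coords_matrix(s)
    if (rigid[m]) {
      # one rigid body for the whole molecule, origin at the COG
      o <- colMeans(xyz)
      body_o[[length(body_o) + 1]] <- matrix(o, 1, 3)
      body_R[[length(body_R) + 1]] <- matrix(c(1,0,0, 0,1,0, 0,0,1), 1, 9)
      if (s$molecule == "dna" && !is.null(s$bodies) &&
          nrow(s$bodies$origin) > 1) {
        len <- max(dist(s$bodies$origin))
        dd <- rod_diffusion(max(len, 1.5 * hr$dna_rod_diameter),
                            hr$dna_rod_diameter,
                            config$temperature, config$viscosity)
      } else {
        dd <- stokes_einstein(hr$protein, config$temperature, config$viscosity)
      }
      bodyDt <- c(bodyDt, dd$Dt); bodyDr <- c(bodyDr, dd$Dr)
      bead_body <- c(bead_body, rep(nbody + 1L, n))
      nbody <- nbody + 1L
    } else if (!is.null(s$bodies)) {
      # flexible DNA: one rigid unit per base pair
      nb <- nrow(s$bodies$origin)
      body_o[[length(body_o) + 1]] <- s$bodies$origin
      body_R[[length(body_R) + 1]] <- s$bodies$R
      bodyDt <- c(bodyDt, rep(se_bp$Dt, nb))
      bodyDr <- c(bodyDr, rep(se_bp$Dr, nb))
      bead_body <- c(bead_body, ifelse(s$bodies$bead_body > 0,
                                       s$bodies$bead_body + nbody, 0L))
      if (!is.null(s$steps)) {
        steps[[length(steps) + 1]] <- s$steps + nbody
        step_par <- step_params_engine(s$params %||% bp_step_params())
      }
      nbody <- nbody + nb
    } else {
      # free beads; hydrodynamic radius = bead radius
      bead_body <- c(bead_body, rep(0L, n))
    }
    if (!is.null(s$springs) && !rigid[m]) {
      sp <- s$springs
      sp$i <- sp$i + nbead
      sp$j <- ifelse(sp$j > 0, sp$j + nbead, 0)
      springs[[length(springs) + 1]] <- sp
    }
    Dbead <- stokes_einstein(pmax(b$radius, 0.05),
                             config$temperature, config$viscosity)$Dt
    beadD <- c(beadD, Dbead)
    mol_id <- c(mol_id, rep(m, n))
    beads[[m]] <- b
    nbead <- nbead + n
  }
  beads <- do.call(rbind, beads)
  beads$index <- seq_len(nrow(beads))
  springs <- if (length(springs)) do.call(rbind, springs) else
    data.frame(i = numeric(0), j = numeric(0), r0 = numeric(0), k = numeric(0))
  steps <- if (length(steps)) do.call(rbind, steps) else
    matrix(integer(0), 0, 2)
  if (is.null(step_par))
    step_par <- list(k6 = rep(1, 6), twist0 = 0, rise0 = 0)
  list(beads = beads, mol = mol_id, bead_body = as.integer(bead_body),
       beadD = beadD,
       body_origin = if (nbody) do.call(rbind, body_o) else matrix(0, 0, 3),
       body_R = if (nbody) do.call(rbind, body_R) else matrix(0, 0, 9),
       bodyDt = bodyDt, bodyDr = bodyDr,
       springs = as.matrix(springs), steps = steps, step_par = step_par,
       molecules = vapply(structures, function(s) s$molecule, character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brownian-dynamics simulation of a CG system
#'
#' Ermak-McCammon-type overdamped Langevin integration: each free bead and
#' each rigid body receives a deterministic drift beta D F dt and Gaussian
#' noise of variance 2 D dt per degree of freedom; rigid units move as rigid
#' bodies (isotropic translational and rotational diffusion).  Trajectories
#' are bit-reproducible for a given seed.
#'
#' @param system a `cg_structure` or a list of two (protein/DNA) structures.
#' @param config a [sim_config()] object.
#' @param elec an [elec_params()] object (inter-molecular nonbonded terms;
#'   intra-molecular nonbonded interactions are not applied).  Defaults to
#'   0.15 M at the configured temperature with the matching water
#'   permittivity; the electrostatic temperature also sets the thermostat.
#' @return object of class `cg_trajectory`: times (ns), frame coordinates,
#'   bead metadata, per-frame energies, the first inter-molecular contact
#'   time (`NA` if none) and full provenance (config, seed).
#' @export
simulate_cg <- function(system, config = sim_config(), elec = NULL) {
  if (is.null(elec))
    elec <- elec_params(0.15, config$temperature,
                        water_permittivity(config$temperature))
  if (abs(elec$temperature - config$temperature) > 1e-6)
    warning("elec_params temperature differs from sim_config temperature; ",
            "the electrostatic temperature sets the thermostat")
  sys <- assemble_system(system, config)
  xyz <- as.matrix(sys$beads[, c("x", "y", "z")])
  res <- cpp_simulate(xyz, sys$beads$radius, sys$beads$charge,
                      as.integer(sys$mol), sys$bead_body, sys$beadD,
                      sys$body_origin, sys$body_R, sys$bodyDt, sys$bodyDr,
                      sys$springs, sys$steps,
                      sys$step_par$k6, sys$step_par$twist0, sys$step_par$rise0,
                      elec$coulomb_prefactor, elec$kappa, elec$cutoff,
                      elec$wca_eps, elec$beta,
                      config$dt, config$n_steps, config$save_stride,
                      config$seed,
                      ifelse(is.na(config$confine_radius), -1,
                             config$confine_radius),
                      config$contact_cutoff, config$stop_on_contact)
  ns <- res$n_saved
  nb <- nrow(sys$beads)
  xyz_arr <- array(res$xyz, dim = c(length(res$times), nb, 3))
  xyz_arr <- xyz_arr[seq_len(ns), , , drop = FALSE]
  en <- as.data.frame(res$energies[seq_len(ns), , drop = FALSE])
  names(en) <- c("bonded", "coulomb", "short_range")
  en$total <- en$bonded + en$coulomb + en$short_range
  meta <- sys$beads
  meta$molecule <- sys$molecules[sys$mol]
  meta$mol <- sys$mol
  structure(list(times = res$times[seq_len(ns)], xyz = xyz_arr,
                 beads = meta, energies = en,
                 first_contact = if (res$first_contact >= 0)
                   res$first_contact else NA_real_,
                 config = config, elec = elec,
                 provenance = sprintf("cgbind %s, seed %d",
                                      as.character(utils::packageVersion("cgbind")),
                                      config$seed)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("CG trajectory: %d frames, %d beads, %.4g ns (dt %.3g ns, seed %d)\n",
              length(x$times), nrow(x$beads), max(x$times),
              x$config$dt, x$config$seed))
  if (!is.na(x$first_contact))
    cat(sprintf("  first inter-molecular contact at %.4g ns\n",
                x$first_contact))
  invisible(x)
}

#' Association event set
#'
#' @param times first-contact times, ns (censored replicas carry the run
#'   length).
#' @param censored logical: no contact within the run.
#' @param conc molecular concentration, mol/L.
#' @param cutoff contact criterion, nm.
#' @param run_length run length, ns.
#' @return object of class `association_events`.
#' @export
association_events <- function(times, censored, conc, cutoff = 0.6,
                               run_length = max(times)) {
  stopifnot(length(times) == length(censored))
  structure(list(times = times, censored = censored, conc = conc,
                 cutoff = cutoff, run_length = run_length),
            class = "association_events")
}

#' @export
print.association_events <- function(x, ...) {
  cat(sprintf("Association events: %d replicas, %d contacts (%.0f%%), [C] = %.3g M\n",
              length(x$times), sum(!x$censored),
              100 * mean(!x$censored), x$conc))
  invisible(x)
}

#' @export
as.data.frame.association_events <- function(x, ...) {
  data.frame(replica = seq_along(x$times), time_ns = x$times,
             censored = x$censored)
}

#' First-contact detection in a trajectory
#'
#' Per replica, the first time at which the minimum inter-molecular
#' surface-to-surface bead distance drops below `cutoff`; censored if it
#' never does.  Works at the resolution of the saved frames.
#'
#' @param traj a two-molecule `cg_trajectory`.
#' @param cutoff contact criterion, nm.
#' @param conc molecular concentration to attach, mol/L.
#' @return an [association_events()] object with one replica.
#' @export
detect_association <- function(traj, cutoff = 0.6, conc = NA_real_) {
  stopifnot(inherits(traj, "cg_trajectory"))
  mols <- unique(traj$beads$mol)
  if (length(mols) < 2)
    stop("trajectory contains a single molecule; association undefined")
  ia <- which(traj$beads$mol == mols[1])
  ib <- which(traj$beads$mol == mols[2])
  ra <- traj$beads$radius[ia]; rb <- traj$beads$radius[ib]
  radsum <- outer(ra, rb, "+")
  nf <- length(traj$times)
  tcontact <- NA_real_
  for (f in seq_len(nf)) {
    A <- matrix(traj$xyz[f, ia, ], ncol = 3)
    B <- matrix(traj$xyz[f, ib, ], ncol = 3)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    surf <- sqrt(pmax(d2, 0)) - radsum
    if (min(surf) < cutoff) { tcontact <- traj$times[f]; break }
  }
  association_events(times = if (is.na(tcontact)) max(traj$times) else tcontact,
                     censored = is.na(tcontact), conc = conc,
                     cutoff = cutoff, run_length = max(traj$times))
}

# smallest half-extent of a structure (for placement feasibility)
min_half_extent <- function(s) {
  xyz <- coords_matrix(s)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xyz, nu = 0)
  # width along the thinnest principal direction + bead radius
  w <- min(apply(abs(xyz %*% sv$v), 2, max))
  w + max(s$beads$radius)
}

#' Spontaneous-association campaign
#'
#' Runs `n_replicas` independent CG simulations of a protein and a DNA
#' fragment, started at a centre-of-geometry separation with distinct
#' uniformly random relative orientations, inside a reflecting confinement
#' sphere that defines the molecular concentration.  First contacts are
#' detected at full time-step resolution with the surface-distance criterion.
#' Replica i uses seed `seed + i - 1`, so any replica can be reproduced by a
#' single-replica campaign with that seed.
#'
#' @param protein,dna `cg_structure` objects.
#' @param n_replicas number of replicas.
#' @param separation initial centre-of-geometry separation, nm.
#' @param t_max run length, ns.
#' @param elec an [elec_params()] object.
#' @param config a [sim_config()]; `n_steps` is derived from `t_max`.
#' @param confine_radius reflecting-sphere radius, nm (sets the molecular
#'   concentration [C] = 1/(N_A V)).
#' @param seed campaign base seed.
#' @param contact_cutoff first-contact criterion, nm.
#' @return an [association_events()] object (attribute `fraction_within`
#'   gives a helper closure on the event times).
#' @export
run_association_campaign <- function(protein, dna, n_replicas = 42,
                                     separation = 6, t_max = 50,
                                     elec = NULL,
                                     config = sim_config(),
                                     confine_radius = 22.5, seed = 1,
                                     contact_cutoff = 0.6) {
  stopifnot(n_replicas >= 1)
  if (is.null(elec))
    elec <- elec_params(0.15, config$temperature,
                        water_permittivity(config$temperature))
  if (separation < min_half_extent(protein) + min_half_extent(dna))
    stop("separation smaller than molecular extent")
  n_steps <- ceiling(t_max / config$dt)
  times <- numeric(n_replicas)
  censored <- logical(n_replicas)
  for (i in seq_len(n_replicas)) {
    seed_i <- seed + i - 1L
    set.seed(seed_i)
    placed <- NULL
    for (try in 1:500) {
      d <- transform_cg(dna, random_rotation(), shift = -cog(dna))
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- transform_cg(protein, random_rotation(),
                        shift = separation * dir - cog(protein))
      e <- interaction_energy(p, d, elec)
      if (e$min_surface_dist > contact_cutoff + 0.2) { placed <- list(p, d); break }
    }
    if (is.null(placed))
      stop("could not place molecules without contact at this separation; ",
           "separation smaller than molecular extent")
    cfg <- config
    cfg$n_steps <- as.integer(n_steps)
    cfg$save_stride <- as.integer(n_steps)   # endpoints only; contacts are
    cfg$seed <- as.integer(seed_i)           # detected at every step
    cfg$stop_on_contact <- TRUE
    cfg$confine_radius <- confine_radius
    cfg$contact_cutoff <- contact_cutoff
    tr <- simulate_cg(list(placed[[2]], placed[[1]]), cfg, elec)
    if (is.na(tr$first_contact)) {
      times[i] <- t_max; censored[i] <- TRUE
    } else {
      times[i] <- tr$first_contact; censored[i] <- FALSE
    }
  }
  vol_nm3 <- 4 / 3 * pi * confine_radius^3
  conc <- 1 / (.NA_AVOGADRO * vol_nm3 * 1e-24)
  association_events(times, censored, conc = conc, cutoff = contact_cutoff,
                     run_length = t_max)
}
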