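# Rigid-body Brownian-dynamics docking, pose clustering, salt scans and the
# Northrup-Allison-McCammon (NAM) association-rate estimator.

#' Docking configuration
#'
#' @param n_runs number of BD trajectories started on the b-surface.
#' @param n_select number of lowest-interaction-energy poses returned.
#' @param b_surface start surface radius (centre-to-centre), nm.
#' @param q_surface truncation surface radius, nm.
#' @param reaction_contacts number of simultaneous inter-molecular contacts
#'   defining a reaction (NAM criterion).
#' @param reaction_distance surface-to-surface contact distance for the
#'   reaction criterion, nm.
#' @param charged_contacts count only ion-pair contacts (charged protein bead
#'   against a phosphate) toward the reaction criterion — the CG analogue of
#'   the polar-atom contact definitions used by atomistic BD docking tools.
#' @param reaction_residues optional author residue numbers restricting which
#'   protein residues count toward the reaction criterion (native-contact
#'   definition: reaction = forming the specific complex through its known
#'   binding face).  `NULL` allows every (charged, if `charged_contacts`)
#'   residue.
#' @param dt base (minimum) time step, ns; far from the DNA the step grows
#'   adaptively up to `dt_max`.
#' @param dt_max maximum time step, ns.
#' @param max_steps per-trajectory step cap.
#' @param temperature temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @param hydro_radius_protein protein hydrodynamic radius, nm.
#' @param seed integer RNG seed.
#' @return object of class `dock_config`.
#' @export
dock_config <- function(n_runs = 20000, n_select = 500, b_surface = 15,
                        q_surface = 30, reaction_contacts = 2,
                        reaction_distance = 0.75, charged_contacts = TRUE,
                        reaction_residues = NULL,
                        dt = 1e-3, dt_max = 0.5,
                        max_steps = 300000, temperature = 310.15,
                        viscosity = water_viscosity(temperature),
                        hydro_radius_protein = 2.0, seed = 1) {
  stopifnot(q_surface > b_surface, n_select <= n_runs, n_runs >= 1)
  structure(as.list(environment()), class = "dock_config")
}

# shared setup: centred beads, diffusion coefficients, electrostatics
dock_setup <- function(protein, dna, ionic_strength, config) {
  stopifnot(inherits(protein, "cg_structure"), inherits(dna, "cg_structure"))
  p <- transform_cg(protein, diag(3), shift = -cog(protein))
  d <- transform_cg(dna, diag(3), shift = -cog(dna))
  pm <- bead_matrix(p); dm <- bead_matrix(d)
  rp <- max(sqrt(rowSums(pm$xyz^2)) + pm$radius)
  rd <- max(sqrt(rowSums(dm$xyz^2)) + dm$radius)
  if (config$b_surface <= rp + rd)
    stop("b_surface must exceed the molecular extent (", round(rp + rd, 1),
         " nm)")
  elec <- elec_params(ionic_strength, config$temperature,
                      water_permittivity(config$temperature))
  sp <- stokes_einstein(config$hydro_radius_protein, config$temperature,
                        config$viscosity)
  dlen <- if (!is.null(d$bodies) && nrow(d$bodies$origin) > 1)
    max(dist(d$bodies$origin)) else 2 * rd
  rodD <- rod_diffusion(max(dlen, 3), 2.0, config$temperature,
                        config$viscosity)
  # DNA axis segment for the engine's distance prefilter
  cen <- dm$xyz
  pc <- svd(sweep(cen, 2, colMeans(cen)), nu = 0)$v[, 1]
  proj <- drop(sweep(cen, 2, colMeans(cen)) %*% pc)
  axis_a <- colMeans(cen) + min(proj) * pc
  axis_b <- colMeans(cen) + max(proj) * pc
  perp <- sweep(cen, 2, colMeans(cen)) - outer(proj, pc)
  axis_rad <- max(sqrt(rowSums(perp^2)) + dm$radius)
  # DNA held fixed; relative translational diffusion = protein + DNA rod
  list(p = p, d = d, pm = pm, dm = dm, rp = rp, rd = rd, elec = elec,
       Dt = sp$Dt + rodD$Dt, Dr = sp$Dr,
       axis_a = axis_a, axis_b = axis_b, axis_rad = axis_rad)
}

run_bd <- function(setup, config) {
  if (isTRUE(config$charged_contacts)) {
    eligible <- setup$pm$charge != 0
    eligible_d <- setup$dm$charge != 0
  } else {
    eligible <- rep(TRUE, length(setup$pm$charge))
    eligible_d <- rep(TRUE, length(setup$dm$charge))
  }
  if (!is.null(config$reaction_residues))
    eligible <- eligible & setup$p$beads$resno %in% config$reaction_residues
  cpp_bd_dock(setup$pm$xyz, setup$pm$radius, setup$pm$charge,
              setup$dm$xyz, setup$dm$radius, setup$dm$charge,
              setup$Dt, setup$Dr,
              setup$elec$coulomb_prefactor, setup$elec$kappa,
              setup$elec$cutoff, setup$elec$wca_eps, setup$elec$beta,
              config$b_surface, config$q_surface, config$dt, config$dt_max,
              config$reaction_contacts, config$reaction_distance,
              as.integer(eligible), as.integer(eligible_d),
              setup$axis_a, setup$axis_b, setup$axis_rad,
              config$n_runs, config$max_steps, config$seed)
}

#' Rigid-body BD docking
#'
#' Launches rigid-body Brownian-dynamics trajectories of the protein from
#' random positions/orientations on the b-surface around the (fixed) DNA,
#' records the minimum-interaction-energy configuration encountered along
#' each trajectory, and returns the `n_select` lowest-energy poses.
#'
#' @param protein,dna `cg_structure` objects (treated as rigid).
#' @param ionic_strength ionic strength, mol/L.
#' @param config a [dock_config()] object.
#' @return object of class `dock_poses`: a ranked pose table (energies in
#'   kJ/mol) plus the rigid transforms of the protein relative to the
#'   DNA-centred frame.
#' @export
bd_dock <- function(protein, dna, ionic_strength = 0.15,
                    config = dock_config()) {
  setup <- dock_setup(protein, dna, ionic_strength, config)
  res <- run_bd(setup, config)
  keep <- which(res$has_pose == 1)
  if (!length(keep))
    stop("no encounter complexes recorded; increase max_steps or lower ",
         "b_surface")
  etot <- res$coulomb[keep] + res$short_range[keep]
  ord <- keep[order(etot)]
  sel <- ord[seq_len(min(config$n_select, length(ord)))]
  data <- data.frame(run = sel,
                     coulomb = res$coulomb[sel],
                     short_range = res$short_range[sel],
                     total = res$coulomb[sel] + res$short_range[sel],
                     cluster = NA_integer_)
  structure(list(data = data,
                 pose_t = res$pose_t[sel, , drop = FALSE],
                 pose_R = res$pose_R[sel, , drop = FALSE],
                 all_energies = sort(res$coulomb[keep] + res$short_range[keep]),
                 n_encounters = length(keep),
                 n_reacted = sum(res$reacted),
                 protein = setup$p, dna = setup$d,
                 ionic_strength = ionic_strength, config = config),
            class = "dock_poses")
}

#' @export
print.dock_poses <- function(x, ...) {
  cat(sprintf("BD docking: %d poses selected of %d encounters (%d runs, I = %g M)\n",
              nrow(x$data), x$n_encounters, x$config$n_runs,
              x$ionic_strength))
  cat(sprintf("  energy range %.3g .. %.3g kJ/mol",
              min(x$data$total), max(x$data$total)))
  if (any(!is.na(x$data$cluster)))
    cat(sprintf("; %d clusters", length(unique(x$data$cluster))))
  cat("\n")
  invisible(x)
}

# protein bead coordinates of pose i (in the DNA frame)
pose_coords <- function(poses, i) {
  R <- matrix(poses$pose_R[i, ], 3, 3, byrow = TRUE)
  sweep(bead_matrix(poses$protein)$xyz %*% t(R), 2, poses$pose_t[i, ], "+")
}

#' Protein structure at a docked pose
#'
#' Returns the protein `cg_structure` placed at pose `i`, in the same
#' (DNA-centred) frame as `poses$dna` — e.g. to start CG simulations from a
#' docked encounter complex.
#'
#' @param poses a `dock_poses` object.
#' @param i pose index.
#' @return a `cg_structure`.
#' @export
pose_structure <- function(poses, i) {
  R <- matrix(poses$pose_R[i, ], 3, 3, byrow = TRUE)
  transform_cg(poses$protein, R, shift = poses$pose_t[i, ],
               about = c(0, 0, 0))
}

#' Recompute the interaction energy of a stored pose
#'
#' Independent re-evaluation of a docked pose's energy decomposition from its
#' stored rigid transform.
#'
#' @param poses a `dock_poses` object.
#' @param i pose index.
#' @return an `energy_decomposition`.
#' @export
pose_energy <- function(poses, i) {
  xyz <- pose_coords(poses, i)
  pm <- bead_matrix(poses$protein); dm <- bead_matrix(poses$dna)
  el <- elec_params(poses$ionic_strength, poses$config$temperature,
                    water_permittivity(poses$config$temperature))
  structure(cpp_interaction_energy(xyz, pm$radius, pm$charge,
                                   dm$xyz, dm$radius, dm$charge,
                                   el$coulomb_prefactor, el$kappa,
                                   el$cutoff, el$wca_eps),
            class = "energy_decomposition")
}

#' Cluster docked poses
#'
#' Hierarchical clustering (average linkage) on the pairwise ligand
#' displacement RMSD of the transformed protein beads; either a fixed number
#' of clusters `k` or an RMSD cut height `h` (nm).  The representative of
#' each cluster is its lowest-energy member.
#'
#' @param poses a `dock_poses` object.
#' @param k number of clusters (overrides `h`).
#' @param h RMSD cut height, nm.
#' @return the `dock_poses` object with cluster ids assigned and an attribute
#'   `representatives` (pose indices, one per cluster).
#' @export
cluster_poses <- function(poses, k = NULL, h = 1.0) {
  n <- nrow(poses$data)
  if (n == 1) {
    poses$data$cluster <- 1L
    attr(poses, "representatives") <- 1L
    return(poses)
  }
  np <- nrow(poses$protein$beads)
  flat <- t(vapply(seq_len(n), function(i) as.vector(pose_coords(poses, i)),
                   numeric(3 * np)))
  dd <- dist(flat) / sqrt(np)             # displacement RMSD
  hc <- hclust(dd, method = "average")
  cl <- if (!is.null(k)) cutree(hc, k = min(k, n)) else cutree(hc, h = h)
  poses$data$cluster <- cl
  reps <- vapply(sort(unique(cl)), function(g) {
    idx <- which(cl == g)
    idx[which.min(poses$data$total[idx])]
  }, integer(1))
  attr(poses, "representatives") <- reps
  poses
}

#' Representative poses
#'
#' @param poses a clustered `dock_poses` object.
#' @return the subset of poses representing each cluster.
#' @export
representative_poses <- function(poses) {
  reps <- attr(poses, "representatives")
  if (is.null(reps)) stop("poses have not been clustered")
  poses$data[reps, ]
}

# Smoluchowski-Debye diffusional rate to a spherical surface at r = a:
# k = 4 pi D / int_a^Inf exp(U(r)/kT) r^-2 dr, U the screened Coulomb
# potential between the net charges.  Returns nm^3/ns.
sd_rate <- function(q1, q2, D_rel, a, elec) {
  pref <- elec$coulomb_prefactor * q1 * q2 * elec$beta  # beta*U = pref*exp(-kr)/r
  kap <- elec$kappa
  integrand <- function(s) {  # s = 1/r
    bu <- pref * s * exp(-kap / s)
    exp(pmin(bu, 700))
  }
  I <- integrate(integrand, 0, 1 / a, rel.tol = 1e-10,
                 subdivisions = 500L)$value
  4 * pi * D_rel / I
}

#' NAM association-rate estimate from BD docking runs
#'
#' Northrup-Allison-McCammon estimator: kon = k_D(b) beta_inf, with k_D the
#' diffusional rate through the b-surface computed by numerical quadrature of
#' the Smoluchowski-Debye integral over the radially averaged (net-charge
#' Debye-Hueckel) interaction potential, and beta_inf the recrossing-corrected
#' probability that a trajectory started at b reacts (forms
#' `reaction_contacts` simultaneous contacts) before escaping through q.
#'
#' @param protein,dna `cg_structure` objects (rigid).
#' @param ionic_strength ionic strength, mol/L.
#' @param config a [dock_config()] object.
#' @return object of class `rate_estimate`: `kon` (M^-1 s^-1) with a 95%
#'   binomial confidence interval, `beta`, `beta_inf`, `kD_b`, `kD_q`.
#' @export
estimate_kon_nam <- function(protein, dna, ionic_strength = 0.15,
                             config = dock_config()) {
  setup <- dock_setup(protein, dna, ionic_strength, config)
  res <- run_bd(setup, config)
  n <- config$n_runs
  beta <- mean(res$reacted)
  q1 <- sum(setup$pm$charge); q2 <- sum(setup$dm$charge)
  kD_b <- sd_rate(q1, q2, setup$Dt, config$b_surface, setup$elec)
  kD_q <- sd_rate(q1, q2, setup$Dt, config$q_surface, setup$elec)
  om <- kD_b / kD_q
  beta_inf_of <- function(b) b / (1 - (1 - b) * om)
  kon_of <- function(b) kD_b * beta_inf_of(b) * .RATE_NM3NS_TO_MS
  se <- sqrt(beta * (1 - beta) / n)
  ci <- c(kon_of(max(0, beta - 1.96 * se)), kon_of(min(1, beta + 1.96 * se)))
  if (beta == 0) {
    warning("no reactions observed; kon = 0 with a wide interval")
    ci <- c(0, kon_of(3 / n))  # rule-of-three upper bound
  }
  structure(list(kon = kon_of(beta), ci = ci, beta = beta,
                 beta_inf = beta_inf_of(beta), kD_b = kD_b * .RATE_NM3NS_TO_MS,
                 kD_q = kD_q * .RATE_NM3NS_TO_MS, n_runs = n,
                 ionic_strength = ionic_strength),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("NAM rate estimate at I = %g M (%d runs):\n", x$ionic_strength,
              x$n_runs))
  cat(sprintf("  kon = %.3g M^-1 s^-1 (95%% CI %.3g .. %.3g), beta = %.3g\n",
              x$kon, x$ci[1], x$ci[2], x$beta))
  invisible(x)
}

#' Docking salt scan
#'
#' Repeats BD docking at a series of ionic strengths with identical seeds and
#' summarizes, per ionic strength, the selected poses, their mean interaction
#' energy and the per-residue contact fractions across poses.
#'
#' @param protein,dna `cg_structure` objects.
#' @param ionic_strengths ionic strengths, mol/L (all > 0).
#' @param config a [dock_config()] object.
#' @param contact_cutoff surface distance defining a pose contact, nm.
#' @return object of class `salt_scan`: list with one element per ionic
#'   strength (`poses`, `mean_energy`, `contact_fraction` by residue).
#' @export
salt_scan <- function(protein, dna, ionic_strengths = c(0.05, 0.15, 0.5, 1),
                      config = dock_config(), contact_cutoff = 0.6) {
  stopifnot(all(ionic_strengths > 0))
  out <- lapply(ionic_strengths, function(I) {
    poses <- bd_dock(protein, dna, ionic_strength = I, config = config)
    cf <- pose_contact_fractions(poses, contact_cutoff)
    list(ionic_strength = I, poses = poses,
         mean_energy = mean(poses$data$total), contact_fraction = cf)
  })
  names(out) <- paste0("I_", ionic_strengths)
  structure(out, class = "salt_scan")
}

#' Per-residue contact fractions over docked poses
#'
#' @param poses a `dock_poses` object.
#' @param cutoff surface-to-surface contact distance, nm.
#' @return data frame with `resno` and `fraction` (share of poses in which
#'   the residue touches the DNA).
#' @export
pose_contact_fractions <- function(poses, cutoff = 0.6) {
  pm <- bead_matrix(poses$protein); dm <- bead_matrix(poses$dna)
  radsum <- outer(pm$radius, dm$radius, "+")
  resno <- poses$protein$beads$resno
  n <- nrow(poses$data)
  hits <- matrix(FALSE, n, length(resno))
  for (i in seq_len(n)) {
    xyz <- pose_coords(poses, i)
    d2 <- outer(rowSums(xyz^2), rowSums(dm$xyz^2), "+") - 2 * xyz %*% t(dm$xyz)
    hits[i, ] <- apply(sqrt(pmax(d2, 0)) - radsum < cutoff, 1, any)
  }
  agg <- tapply(colMeans(hits), resno, mean)
  data.frame(resno = as.integer(names(agg)), fraction = as.numeric(agg))
}
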