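# Synthetic inputs: ideal B-DNA, an A1-like charged helical bundle, planted
# trajectories with known contact schedules, and parametric datasets with
# known ground truth for the fitting routines.

#' Demo nucleotide sequences
#'
#' Fixed synthetic sequences used throughout the examples and tests: a 42-bp
#' mixed-composition duplex (`"ds42"`), a 42-bp alternating AT duplex
#' (`"polyAT42"`), and a 23-bp fragment (`"ds23"`).  The CG DNA topology
#' (bead counts, charges) is sequence-independent; these merely provide
#' reproducible inputs of the lengths studied.
#'
#' @param name one of `"ds42"`, `"polyAT42"`, `"ds23"`.
#' @return a character string (one strand, 5'->3').
#' @export
demo_sequence <- function(name = c("ds42", "polyAT42", "ds23")) {
  name <- match.arg(name)
  switch(name,
         ds42 = "GGCAGTACGTTAGCCATGCTAGGTACCGAATTCGCGATCGAT",
         polyAT42 = strrep("AT", 21),
         ds23 = "ATCGGCTAATCGGCAATGCCGTA")
}

#' Ideal B-DNA generator
#'
#' Front-end to [build_dna_cg()] with ideal straight B-DNA frames (rest rise
#' and twist from the step parameters), i.e. the minimum-energy conformation
#' of the rigid base-pair chain.
#'
#' @param sequence nucleotide sequence (ACGT).
#' @param params a [bp_step_params()] object.
#' @return a DNA `cg_structure`.
#' @export
generate_bdna <- function(sequence, params = bp_step_params()) {
  build_dna_cg(sequence, params)
}

#' Mock A1-like protein generator
#'
#' Builds a coarse-grained helical bundle emulating the electrostatic surface
#' of the vWF A1 domain: four helices plus loops/tails spanning author
#' residues 1325-1419, with an arginine triad (R1392/R1395/R1399) forming a
#' contiguous surface patch on one helix, the adjacent lysine patch
#' K1405-K1408 on the same helix, the distal arginine R1336 on the
#' N-terminal segment (> 2.5 nm from the triad centroid), and two distal
#' glutamates tuning the net charge to the target (+6e by default).
#'
#' @param seed RNG seed (adds a small reproducible coordinate jitter).
#' @param net_charge target net charge, e.
#' @param jitter amplitude of the Gaussian coordinate jitter, nm.
#' @param cutoff,k_spring elastic-network parameters, see
#'   [build_protein_cg()].
#' @return a protein `cg_structure` with author numbering 1325-1419.
#' @examples
#' a1 <- generate_mock_a1()
#' net_charge(a1)  # +6
#' @export
generate_mock_a1 <- function(seed = 1, net_charge = 6, jitter = 0.005,
                             cutoff = 1.0, k_spring = 500) {
  rise <- 0.146; hrad <- 0.23; turn <- 100 * pi / 180
  helix <- function(n, corner, z0, dzsign, phase_deg) {
    k <- seq_len(n) - 1
    a <- phase_deg * pi / 180 + k * turn
    cbind(corner[1] + hrad * cos(a), corner[2] + hrad * sin(a),
          z0 + dzsign * rise * k)
  }
  lin <- function(from, to, n) {
    t <- seq_len(n) / (n + 1)
    cbind(from[1] + t * (to[1] - from[1]),
          from[2] + t * (to[2] - from[2]),
          from[3] + t * (to[3] - from[3]))
  }
  s <- 2.2
  h1 <- helix(18, c(0, 0), 0, +1, 250 - 11 * 100)      # 1325-1342 (1336 at k=11)
  h2 <- helix(18, c(s, 0), 2.48, -1, 0)                # 1348-1365
  h3 <- helix(13, c(s, s), 0, +1, 90)                  # 1371-1383
  h4 <- helix(23, c(0, s), 3.21, -1, 322)              # 1390-1412 (triad k=2,5,9)
  l1 <- lin(h1[18, ], h2[1, ], 5)                      # 1343-1347
  l2 <- lin(h2[18, ], h3[1, ], 5)                      # 1366-1370
  l3 <- lin(h3[13, ], h4[1, ], 6)                      # 1384-1389
  tl <- lin(h4[23, ], c(-1.0, s + 1.0, -0.4), 7)       # 1413-1419
  xyz <- rbind(h1, l1, h2, l2, h3, l3, h4, tl)
  resno <- 1325:1419
  stopifnot(nrow(xyz) == length(resno))
  resid <- rep("ALA", length(resno))
  resid[resno %in% c(1336, 1392, 1395, 1399)] <- "ARG"
  resid[resno %in% 1405:1408] <- "LYS"
  n_pos <- sum(resid %in% c("ARG", "LYS"))
  n_neg <- n_pos - net_charge
  if (n_neg < 0 || n_neg > 2)
    stop("infeasible net-charge target for the default charged-site layout")
  if (n_neg >= 1) resid[resno == 1352] <- "GLU"
  if (n_neg >= 2) resid[resno == 1374] <- "GLU"
  set.seed(seed)
  xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter), ncol = 3)
  st <- build_protein_cg(xyz, resno = resno, resid = resid,
                         cutoff = cutoff, k_spring = k_spring)
  # placement constraints of the mock
  triad <- as.matrix(st$beads[st$beads$resno %in% c(1392, 1395, 1399),
                              c("x", "y", "z")])
  if (max(dist(triad)) >= 1.5)
    stop("infeasible placement: triad not mutually within 1.5 nm")
  r1336 <- as.numeric(st$beads[st$beads$resno == 1336, c("x", "y", "z")])
  if (sqrt(sum((r1336 - colMeans(triad))^2)) <= 2.5)
    stop("infeasible placement: R1336 not distal from the triad")
  if (net_charge(st) != net_charge)
    stop("infeasible placement: net charge mismatch")
  st
}

#' Planted trajectory with a known contact schedule
#'
#' Builds a synthetic two-molecule trajectory in which the DNA fragment
#' touches prescribed protein residues in prescribed frames (end-on approach
#' along the residue's outward normal) and is far away otherwise.  The
#' realized schedule is verified frame by frame against the contact
#' criterion; an unrealizable schedule raises an error.
#'
#' @param protein,dna `cg_structure` objects.
#' @param schedule data frame with columns `resno`, `from`, `to` (frame
#'   ranges, 1-based, inclusive); rows sharing frames put their residues in
#'   contact simultaneously (residues must be clustered).  An empty schedule
#'   yields no contacts.
#' @param n_frames number of frames.
#' @param noise Gaussian positional jitter per frame, nm.
#' @param seed RNG seed.
#' @param cutoff contact criterion used for verification, nm.
#' @param dt_save time between frames, ns.
#' @return a `cg_trajectory`.
#' @export
generate_planted_trajectory <- function(protein, dna, schedule = NULL,
                                        n_frames = 100, noise = 0, seed = 1,
                                        cutoff = 0.6, dt_save = 0.01) {
  set.seed(seed)
  pb <- protein$beads
  pxyz <- coords_matrix(protein)
  pcog <- colMeans(pxyz)
  # DNA oriented end-on: principal axis along +z, first bp core at the top
  dxyz <- coords_matrix(dna)
  bp_idx <- which(dna$beads$group == "bp")
  ax <- svd(sweep(dxyz[bp_idx, , drop = FALSE], 2,
                  colMeans(dxyz[bp_idx, , drop = FALSE])), nu = 0)$v[, 1]
  chain_dir <- dxyz[bp_idx[length(bp_idx)], ] - dxyz[bp_idx[1], ]
  if (sum(ax * chain_dir) < 0) ax <- -ax
  end_bead <- bp_idx[1]
  far_extent <- max(dist(rbind(pcog, dxyz))) + max(dna$beads$radius)

  active_res <- vector("list", n_frames)
  if (!is.null(schedule) && nrow(schedule)) {
    for (r in seq_len(nrow(schedule))) {
      fr <- schedule$from[r]:schedule$to[r]
      if (any(fr < 1 | fr > n_frames)) stop("schedule frames out of range")
      for (f in fr) active_res[[f]] <- c(active_res[[f]], schedule$resno[r])
    }
  }
  nb_d <- nrow(dna$beads)
  frames <- array(0, c(n_frames, nrow(pb) + nb_d, 3))
  dr_end <- dna$beads$radius[end_bead]
  for (f in seq_len(n_frames)) {
    res <- active_res[[f]]
    if (length(res)) {
      tb <- which(pb$resno %in% res & pb$group == "residue")
      if (!length(tb)) stop("scheduled residue not present in the protein")
      target <- colMeans(pxyz[tb, , drop = FALSE])
      nrm <- target - pcog
      nrm <- nrm / sqrt(sum(nrm^2))
      gap <- 0.25
      # chain extends outward along the normal; the first bp faces the protein
      R <- rotation_between(ax, nrm)
      pos_end <- target + (max(pb$radius[tb]) + dr_end + gap) * nrm
      dn <- sweep(dxyz, 2, dxyz[end_bead, ]) %*% t(R)
      dn <- sweep(dn, 2, pos_end, FUN = "+")
    } else {
      dn <- sweep(dxyz, 2, dxyz[end_bead, ])
      dn <- sweep(dn, 2, pcog + c(far_extent + 3, 0, 0), FUN = "+")
    }
    fx <- rbind(pxyz, dn)
    if (noise > 0) fx <- fx + matrix(rnorm(length(fx), sd = noise), ncol = 3)
    frames[f, , ] <- fx
  }
  beads <- rbind(
    cbind(pb, molecule = "protein", mol = 1),
    cbind(dna$beads, molecule = "dna", mol = 2))
  beads$index <- seq_len(nrow(beads))
  traj <- structure(list(times = (seq_len(n_frames) - 1) * dt_save,
                         xyz = frames, beads = beads,
                         energies = NULL, first_contact = NA_real_,
                         config = list(seed = seed, dt = dt_save),
                         provenance = "planted trajectory"),
                    class = "cg_trajectory")
  # verify the realized schedule with the same contact rule
  prof_ok <- verify_schedule(traj, active_res, cutoff)
  if (!prof_ok)
    stop("infeasible schedule: realized contacts do not match the plan")
  traj
}

# rotation taking unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  w <- c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3], u[1]*v[2] - u[2]*v[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

verify_schedule <- function(traj, active_res, cutoff) {
  ip <- which(traj$beads$mol == 1)
  id <- which(traj$beads$mol == 2)
  ra <- traj$beads$radius[ip]; rb <- traj$beads$radius[id]
  resno <- traj$beads$resno[ip]
  for (f in seq_along(active_res)) {
    sd <- surface_dist(frame_coords(traj, f, ip), frame_coords(traj, f, id),
                       ra, rb)
    touched <- sort(unique(resno[apply(sd < cutoff, 1, any)]))
    planned <- sort(unique(active_res[[f]]))
    if (!identical(as.integer(touched), as.integer(planned))) return(FALSE)
  }
  TRUE
}

#' Synthetic datasets with known ground truth
#'
#' Samples from exactly the generative model the corresponding fit assumes;
#' the ground truth is returned alongside the data.
#'
#' @param kind one of `"event_times"`, `"isotherm"`, `"salt_series"`,
#'   `"fcs"`.
#' @param n number of observations (events or curve points).
#' @param noise noise level (standard deviation; interpretation per kind:
#'   absolute signal sd for isotherm, sd of log10 Ka for salt series,
#'   relative sd for FCS; ignored for event times).
#' @param seed RNG seed.
#' @param ... ground-truth parameters overriding the defaults:
#'   \describe{
#'     \item{event_times}{`kon` (M^-1 s^-1), `conc` (M), `t_max` (ns,
#'       censoring horizon).}
#'     \item{isotherm}{`Kd`, `amplitude`, `offset`, `conc_range` (M).}
#'     \item{salt_series}{`b`, `a`, `salts` (M).}
#'     \item{fcs}{`f`, `tauD1`, `tauD2`, `N`, `s`, `lag_range` (s).}
#'   }
#' @return list with `data` (an [association_events()] object or a data
#'   frame) and `truth` (named list).
#' @export
generate_datasets <- function(kind = c("event_times", "isotherm",
                                       "salt_series", "fcs"),
                              n = 100, noise = 0, seed = 1, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  opts <- list(...)
  get <- function(name, default) opts[[name]] %||% default
  switch(kind,
    event_times = {
      kon <- get("kon", 5.7e11); conc <- get("conc", 3.5e-5)
      t_max <- get("t_max", Inf)
      rate <- kon * conc * 1e-9                  # ns^-1
      t <- rexp(n, rate)
      cens <- t > t_max
      t[cens] <- t_max
      list(data = association_events(t, cens, conc = conc,
                                     run_length = if (is.finite(t_max)) t_max
                                     else max(t)),
           truth = list(kon = kon, conc = conc, rate = rate))
    },
    isotherm = {
      Kd <- get("Kd", 1e-5); amp <- get("amplitude", 1)
      off <- get("offset", 0)
      cr <- get("conc_range", c(Kd / 50, Kd * 50))
      conc <- exp(seq(log(cr[1]), log(cr[2]), length.out = n))
      y <- off + amp * conc / (conc + Kd) + rnorm(n, sd = noise)
      list(data = data.frame(conc = conc, signal = y),
           truth = list(Kd = Kd, amplitude = amp, offset = off))
    },
    salt_series = {
      b <- get("b", -6); a <- get("a", -2)
      salts <- get("salts", exp(seq(log(0.02), log(0.2), length.out = n)))
      logKa <- a + b * log10(salts) + rnorm(length(salts), sd = noise)
      list(data = data.frame(salt = salts, Kd = 10^(-logKa)),
           truth = list(b = b, a = a))
    },
    fcs = {
      f <- get("f", 0.21); tauD1 <- get("tauD1", 1e-4)
      tauD2 <- get("tauD2", 1e-3); N <- get("N", 1); s <- get("s", 5)
      lr <- get("lag_range", c(1e-6, 1))
      lag <- exp(seq(log(lr[1]), log(lr[2]), length.out = n))
      G <- (1 / N) * ((1 - f) * fcs_g1(lag, tauD1, s) +
                        f * fcs_g1(lag, tauD2, s))
      G <- G * (1 + rnorm(n, sd = noise))
      list(data = data.frame(lag = lag, G = G),
           truth = list(f = f, tauD1 = tauD1, tauD2 = tauD2, N = N, s = s))
    })
}
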