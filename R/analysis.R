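# Trajectory and pose-set analysis: contact profiles, region classification,
# occupancy density grids, DNA bending angles, RMSF and the resampled KS test.

# frame coordinates of bead subset as a matrix
frame_coords <- function(traj, f, idx = seq_len(nrow(traj$beads))) {
  matrix(traj$xyz[f, idx, ], ncol = 3)
}

# per-frame logical contact matrix helpers ----------------------------------

# surface-to-surface distance matrix between two bead sets
surface_dist <- function(A, B, ra, rb) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0)) - outer(ra, rb, "+")
}

# beads of molecule m
mol_idx <- function(traj, which = 1) {
  mols <- sort(unique(traj$beads$mol))
  if (length(mols) < 2) stop("trajectory must contain two molecules")
  which(traj$beads$mol == mols[which])
}

#' Contact profile of a two-molecule trajectory
#'
#' Fraction of frames in which each protein residue (and each DNA base pair)
#' has any inter-molecular bead pair closer than `cutoff`
#' (surface-to-surface).
#'
#' @param traj a two-molecule `cg_trajectory`.
#' @param cutoff contact criterion, nm.
#' @return object of class `contact_profile`: list of data frames `residue`
#'   and `basepair` with per-entity contact fractions in `[0, 1]`.
#' @export
contact_profile <- function(traj, cutoff = 0.6) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- length(traj$times)
  if (nf == 0) stop("empty trajectory")
  ip <- which(traj$beads$molecule == "protein")
  id <- which(traj$beads$molecule == "dna")
  if (!length(ip) || !length(id)) {
    # generic two-molecule system: first = "residue", second = "basepair"
    ip <- mol_idx(traj, 1); id <- mol_idx(traj, 2)
  }
  ra <- traj$beads$radius[ip]; rb <- traj$beads$radius[id]
  res_p <- traj$beads$resno[ip]; res_d <- traj$beads$resno[id]
  up <- sort(unique(res_p)); ud <- sort(unique(res_d))
  cnt_p <- setNames(numeric(length(up)), up)
  cnt_d <- setNames(numeric(length(ud)), ud)
  for (f in seq_len(nf)) {
    sd <- surface_dist(frame_coords(traj, f, ip), frame_coords(traj, f, id),
                       ra, rb)
    hit <- sd < cutoff
    pr <- tapply(apply(hit, 1, any), res_p, any)
    dr <- tapply(apply(hit, 2, any), res_d, any)
    cnt_p[names(pr)] <- cnt_p[names(pr)] + pr
    cnt_d[names(dr)] <- cnt_d[names(dr)] + dr
  }
  structure(list(
    residue = data.frame(resno = as.integer(names(cnt_p)),
                         fraction = as.numeric(cnt_p) / nf),
    basepair = data.frame(bp = as.integer(names(cnt_d)),
                          fraction = as.numeric(cnt_d) / nf),
    cutoff = cutoff, n_frames = nf), class = "contact_profile")
}

#' Classify protein-DNA contacts by binding region
#'
#' Assigns each frame to exactly one category according to which protein
#' regions hold contacts: `region1` only, `region2` only, `both`,
#' `lysine_patch` (no arginine-region contact), `other` (any other residue)
#' or `none`.  The fractions sum to 1.
#'
#' @param traj a two-molecule `cg_trajectory`.
#' @param region_map a [region_map_a1()] object.
#' @param cutoff contact criterion, nm.
#' @return named numeric vector of frame fractions.
#' @export
classify_regions <- function(traj, region_map = region_map_a1(),
                             cutoff = 0.6) {
  stopifnot(inherits(traj, "cg_trajectory"))
  ip <- which(traj$beads$molecule == "protein")
  id <- which(traj$beads$molecule == "dna")
  if (!length(ip) || !length(id)) {
    ip <- mol_idx(traj, 1); id <- mol_idx(traj, 2)
  }
  resno <- traj$beads$resno[ip]
  ra <- traj$beads$radius[ip]; rb <- traj$beads$radius[id]
  cats <- c("region1", "region2", "both", "lysine_patch", "other", "none")
  counts <- setNames(numeric(6), cats)
  nf <- length(traj$times)
  for (f in seq_len(nf)) {
    sd <- surface_dist(frame_coords(traj, f, ip), frame_coords(traj, f, id),
                       ra, rb)
    touched <- unique(resno[apply(sd < cutoff, 1, any)])
    r1 <- any(touched %in% region_map$region1)
    r2 <- any(touched %in% region_map$region2)
    lys <- any(touched %in% region_map$lysine_patch)
    cat_f <- if (r1 && r2) "both" else if (r1) "region1" else if (r2)
      "region2" else if (lys) "lysine_patch" else if (length(touched))
      "other" else "none"
    counts[cat_f] <- counts[cat_f] + 1
  }
  counts / nf
}

# Kabsch superposition -------------------------------------------------------

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `from` onto `to`
#' (no reflection).
#'
#' @param from,to n x 3 coordinate matrices.
#' @return list with `R` (3x3 rotation), `t` (translation applied after
#'   rotation) and `rmsd` (nm).
#' @export
superpose_transform <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3)
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(R = R, t = ct - drop(R %*% cf), rmsd = rmsd)
}

#' Occupancy density grid
#'
#' Time-averaged spatial density of one molecule around the other: all frames
#' (or docked poses) are least-squares superposed on the reference molecule,
#' partner bead positions are accumulated on a cubic grid, and the grid is
#' z-normalized to sigma units (mean 0, standard deviation 1 over the grid).
#'
#' @param x a two-molecule `cg_trajectory` or a `dock_poses` object.
#' @param reference which molecule to superpose on: `"protein"` or `"dna"`.
#' @param voxel voxel edge, nm.
#' @param pad padding added around the partner's bounding box, nm.
#' @param ... unused.
#' @return object of class `density_grid`: `origin`, `voxel`, `dim`,
#'   z-normalized `values` array, plus the raw `counts`.
#' @export
occupancy_density <- function(x, reference = c("protein", "dna"), voxel = 0.2,
                              pad = 0.5, ...) {
  UseMethod("occupancy_density")
}

#' @export
occupancy_density.cg_trajectory <- function(x, reference = c("protein", "dna"),
                                            voxel = 0.2, pad = 0.5, ...) {
  reference <- match.arg(reference)
  iref <- which(x$beads$molecule == reference)
  if (!length(iref)) iref <- mol_idx(x, if (reference == "protein") 1 else 2)
  ipart <- setdiff(seq_len(nrow(x$beads)), iref)
  ref0 <- frame_coords(x, 1, iref)
  check_alignment_selection(ref0)
  nf <- length(x$times)
  pts <- vector("list", nf)
  for (f in seq_len(nf)) {
    tr <- superpose_transform(frame_coords(x, f, iref), ref0)
    pts[[f]] <- sweep(frame_coords(x, f, ipart) %*% t(tr$R), 2, tr$t, "+")
  }
  grid_from_points(do.call(rbind, pts), voxel, pad)
}

#' @export
occupancy_density.dock_poses <- function(x, reference = c("dna", "protein"),
                                         voxel = 0.2, pad = 0.5, ...) {
  reference <- match.arg(reference)
  n <- nrow(x$data)
  if (reference == "dna") {
    pts <- do.call(rbind, lapply(seq_len(n), function(i) pose_coords(x, i)))
  } else {
    # DNA beads expressed in the protein body frame of each pose
    dxyz <- bead_matrix(x$dna)$xyz
    pts <- do.call(rbind, lapply(seq_len(n), function(i) {
      R <- matrix(x$pose_R[i, ], 3, 3, byrow = TRUE)
      sweep(dxyz, 2, x$pose_t[i, ]) %*% R
    }))
  }
  grid_from_points(pts, voxel, pad)
}

check_alignment_selection <- function(xyz) {
  if (nrow(xyz) < 3) stop("alignment selection needs >= 3 beads")
  sv <- svd(sweep(xyz, 2, colMeans(xyz)), nu = 0)
  if (sum(sv$d > 1e-8) < 2)
    stop("degenerate alignment selection (collinear beads)")
  invisible(TRUE)
}

grid_from_points <- function(pts, voxel, pad) {
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dims <- pmax(ceiling((hi - lo) / voxel), 1)
  ix <- pmin(pmax(floor(sweep(pts, 2, lo) / voxel) + 1, 1),
             matrix(dims, nrow(pts), 3, byrow = TRUE))
  counts <- array(0, dims)
  idx <- ix[, 1] + dims[1] * (ix[, 2] - 1) + dims[1] * dims[2] * (ix[, 3] - 1)
  tab <- tabulate(idx, nbins = prod(dims))
  counts[] <- tab
  sdv <- sd(as.numeric(counts))
  values <- if (sdv > 0) (counts - mean(counts)) / sdv else counts * 0
  structure(list(origin = lo, voxel = voxel, dim = dims,
                 values = values, counts = counts),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Occupancy density grid: %d x %d x %d voxels of %g nm (sigma units)\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel))
  cat(sprintf("  max %.2f sigma at voxel (%s)\n", max(x$values),
              paste(which(x$values == max(x$values), arr.ind = TRUE)[1, ],
                    collapse = ", ")))
  invisible(x)
}

#' DNA bending angle
#'
#' Angle between the helical-axis vectors of the first and second halves of
#' the fragment; each half-axis is the first principal axis of its base-pair
#' origins (core beads), oriented along the chain.
#'
#' @param x a DNA `cg_structure`, or a `cg_trajectory` containing a DNA
#'   molecule (base-pair core beads are used).
#' @return object of class `bending_sample`: numeric vector of angles in
#'   degrees (0..180), one per frame.
#' @export
bending_angle <- function(x) {
  if (inherits(x, "cg_structure")) {
    bp <- x$beads[x$beads$group == "bp", ]
    mats <- list(as.matrix(bp[order(bp$resno), c("x", "y", "z")]))
  } else if (inherits(x, "cg_trajectory")) {
    idx <- which(x$beads$group == "bp")
    if (!length(idx)) stop("trajectory has no base-pair core beads")
    idx <- idx[order(x$beads$resno[idx])]
    mats <- lapply(seq_along(x$times), function(f) frame_coords(x, f, idx))
  } else stop("x must be a cg_structure or cg_trajectory")
  n <- nrow(mats[[1]])
  if (n < 8) stop("bending angle needs >= 8 base pairs")
  h1 <- seq_len(floor(n / 2))
  h2 <- seq(n - floor(n / 2) + 1, n)
  ang <- vapply(mats, function(m) half_axis_angle(m, h1, h2), numeric(1))
  structure(ang, class = "bending_sample",
            definition = "half-fragment principal axes")
}

half_axis_angle <- function(m, h1, h2) {
  ax <- function(idx) {
    sub <- m[idx, , drop = FALSE]
    sv <- svd(sweep(sub, 2, colMeans(sub)), nu = 0)
    v <- sv$v[, 1]
    dirs <- sub[nrow(sub), ] - sub[1, ]
    if (sum(v * dirs) < 0) v <- -v
    v
  }
  ct <- max(-1, min(1, sum(ax(h1) * ax(h2))))
  acos(ct) * 180 / pi
}

#' @export
print.bending_sample <- function(x, ...) {
  cat(sprintf("Bending angles: %d frames, mean %.1f deg, mode %.1f deg\n",
              length(x), mean(x), bending_mode(x)))
  invisible(x)
}

#' Mode of a bending-angle distribution
#'
#' Kernel-density mode of the per-frame bending angles.
#'
#' @param x a `bending_sample` (or numeric vector of angles, degrees).
#' @return the modal angle in degrees.
#' @export
bending_mode <- function(x) {
  if (length(x) < 2) return(as.numeric(x)[1])
  d <- density(as.numeric(x), from = 0)
  d$x[which.max(d$y)]
}

#' Root-mean-square fluctuation per bead
#'
#' RMSF after optional least-squares superposition of every frame onto the
#' first frame.
#'
#' @param traj a `cg_trajectory`.
#' @param align superpose frames before computing fluctuations?
#' @param selection bead indices used for the superposition (default: all).
#' @return numeric vector, per-bead RMSF in nm.
#' @export
rmsf <- function(traj, align = TRUE, selection = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- length(traj$times)
  if (nf < 2) stop("RMSF needs >= 2 frames")
  nb <- nrow(traj$beads)
  if (is.null(selection)) selection <- seq_len(nb)
  frames <- lapply(seq_len(nf), function(f) frame_coords(traj, f))
  if (align) {
    ref <- frames[[1]][selection, , drop = FALSE]
    frames <- lapply(frames, function(m) {
      tr <- superpose_transform(m[selection, , drop = FALSE], ref)
      sweep(m %*% t(tr$R), 2, tr$t, "+")
    })
  }
  arr <- simplify2array(frames)              # nb x 3 x nf
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  sqrt(apply(dev2, 1, mean) * 3)             # mean over (3*nf) -> 3D rms
}

#' Resampled two-sample Kolmogorov-Smirnov test
#'
#' Repeatedly subsamples (without replacement) `nA` and `nB` values from two
#' samples, applies the two-sample KS test, and reports the fraction of
#' rounds with p >= alpha.
#'
#' @param sampleA,sampleB numeric samples.
#' @param nA,nB subsample sizes (must not exceed the sample sizes).
#' @param rounds number of resampling rounds.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return object of class `resample_result`: `fraction_pass`, the p-values,
#'   and the test parameters.
#' @export
ks_resample <- function(sampleA, sampleB, nA, nB, rounds = 200, alpha = 0.05,
                        seed = 1) {
  if (nA > length(sampleA) || nB > length(sampleB))
    stop("subsample size exceeds sample size")
  set.seed(seed)
  p <- vapply(seq_len(rounds), function(r) {
    suppressWarnings(ks.test(sample(sampleA, nA), sample(sampleB, nB))$p.value)
  }, numeric(1))
  structure(list(fraction_pass = mean(p >= alpha), p_values = p,
                 rounds = rounds, alpha = alpha, nA = nA, nB = nB,
                 seed = seed),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("KS resampling: p >= %g in %.0f%% of %d rounds (nA = %d, nB = %d)\n",
              x$alpha, 100 * x$fraction_pass, x$rounds, x$nA, x$nB))
  invisible(x)
}
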