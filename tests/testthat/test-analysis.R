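test_that("contact profiles match planted schedules and a brute-force count", {
  prot <- ring_protein()
  dna <- dna42()
  sched <- data.frame(resno = 105, from = 1, to = 50)
  tr <- generate_planted_trajectory(prot, dna, sched, n_frames = 100)
  cp <- contact_profile(tr)
  expect_equal(cp$residue$fraction[cp$residue$resno == 105], 0.5)
  expect_true(all(cp$residue$fraction[cp$residue$resno != 105] == 0))
  expect_true(all(cp$residue$fraction >= 0 & cp$residue$fraction <= 1))
  expect_true(all(cp$basepair$fraction >= 0 & cp$basepair$fraction <= 1))

  # no contacts anywhere
  tr0 <- generate_planted_trajectory(prot, dna, NULL, n_frames = 20)
  cp0 <- contact_profile(tr0)
  expect_true(all(cp0$residue$fraction == 0))
  expect_true(all(cp0$basepair$fraction == 0))

  # 10-frame toy system vs frame-by-frame hand count
  d <- c(0.1, 2, 0.5, 0.7, 0.3, 1, 0.55, 0.61, 0.2, 5)
  toy <- toy_trajectory(d)
  got <- contact_profile(toy, cutoff = 0.6)
  expect_equal(got$residue$fraction, mean(d < 0.6))
})

test_that("contact fractions are invariant under global rigid motion", {
  prot <- ring_protein()
  dna <- dna42()
  tr <- generate_planted_trajectory(prot, dna,
                                    data.frame(resno = 103, from = 1, to = 30),
                                    n_frames = 60)
  base <- contact_profile(tr)
  set.seed(4)
  for (f in seq_along(tr$times)) {
    R <- test_rotation(); shift <- rnorm(3) * 5
    m <- matrix(tr$xyz[f, , ], ncol = 3)
    tr$xyz[f, , ] <- sweep(m %*% t(R), 2, shift, "+")
  }
  moved <- contact_profile(tr)
  expect_equal(moved$residue$fraction, base$residue$fraction)
})

test_that("frames are classified into exclusive binding-region categories", {
  prot <- ring_protein(charges = c(5, 8))  # ARG at resno 105 and 108
  dna <- dna42()
  rmap <- region_map_a1(region1 = 105, region2 = 108, lysine_patch = 110)
  sched <- rbind(data.frame(resno = 105, from = 1, to = 30),
                 data.frame(resno = 108, from = 31, to = 60))
  tr <- generate_planted_trajectory(prot, dna, sched, n_frames = 60)
  fr <- classify_regions(tr, rmap)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["region1"]), 0.5)
  expect_equal(unname(fr["region2"]), 0.5)
  expect_equal(unname(fr["both"] + fr["lysine_patch"] + fr["other"] +
                        fr["none"]), 0)

  # partition property on an arbitrary trajectory
  tr2 <- generate_planted_trajectory(prot, dna, NULL, n_frames = 10)
  expect_equal(sum(classify_regions(tr2, rmap)), 1)
})

test_that("superposition recovers exact transforms", {
  set.seed(21)
  X <- matrix(rnorm(30), 10, 3)
  idt <- superpose_transform(X, X)
  expect_lt(idt$rmsd, 1e-12)
  expect_equal(idt$R, diag(3), tolerance = 1e-12)

  R <- test_rotation(); t <- c(1, -2, 0.5)
  Y <- sweep(X %*% t(R), 2, t, "+")
  tr <- superpose_transform(X, Y)
  # recovered rotation within 1e-6 rad of the applied one
  ang <- acos(pmin(1, (sum(diag(t(tr$R) %*% R)) - 1) / 2))
  expect_lt(ang, 1e-6)
  expect_lt(tr$rmsd, 1e-10)
})

test_that("occupancy grids are exactly sigma-normalized with sane extremes", {
  prot <- ring_protein()
  dna <- dna42()
  tr <- generate_planted_trajectory(prot, dna,
                                    data.frame(resno = 105, from = 1, to = 40),
                                    n_frames = 40)
  g <- occupancy_density(tr, reference = "protein", voxel = 0.4)
  expect_lt(abs(mean(g$values)), 1e-6)
  expect_equal(sd(as.numeric(g$values)), 1, tolerance = 1e-6)

  # planted hotspot: a partner bead fixed at one location across frames
  nf <- 50
  xyz <- array(0, c(nf, 5, 3))
  anchor <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2), 4, 3, byrow = TRUE)
  for (f in 1:nf) {
    xyz[f, 1:4, ] <- anchor
    xyz[f, 5, ] <- c(1, 1, 1)
  }
  beads <- data.frame(index = 1:5, label = "X", resno = 1:5,
                      x = 0, y = 0, z = 0, radius = 0.3, charge = 0,
                      group = "bead", molecule = c(rep("protein", 4), "dna"),
                      mol = c(1, 1, 1, 1, 2))
  tr2 <- structure(list(times = seq_len(nf) - 1, xyz = xyz, beads = beads,
                        config = list(seed = 0, dt = 1)),
                   class = "cg_trajectory")
  g2 <- occupancy_density(tr2, reference = "protein", voxel = 0.25)
  peak <- which(g2$counts == max(g2$counts), arr.ind = TRUE)
  centre <- g2$origin + (peak[1, ] - 0.5) * g2$voxel
  expect_lt(max(abs(centre - c(1, 1, 1))), g2$voxel)

  # uniformly random placements stay below 5 sigma at 1e4 frames
  nf <- 10000
  xyz <- array(0, c(nf, 5, 3))
  set.seed(8)
  for (f in 1:nf) {
    xyz[f, 1:4, ] <- anchor
    xyz[f, 5, ] <- runif(3, -2, 2)
  }
  tr3 <- structure(list(times = seq_len(nf) - 1, xyz = xyz, beads = beads,
                        config = list(seed = 0, dt = 1)),
                   class = "cg_trajectory")
  g3 <- occupancy_density(tr3, reference = "protein", voxel = 0.5, pad = 0)
  expect_lt(max(abs(g3$values)), 5)
})

test_that("degenerate alignment selections are rejected", {
  nf <- 3
  xyz <- array(0, c(nf, 4, 3))
  for (f in 1:nf) xyz[f, , 1] <- 1:4   # collinear reference
  beads <- data.frame(index = 1:4, label = "X", resno = 1:4, x = 0, y = 0,
                      z = 0, radius = 0.3, charge = 0, group = "bead",
                      molecule = c("protein", "protein", "protein", "dna"),
                      mol = c(1, 1, 1, 2))
  tr <- structure(list(times = 1:nf, xyz = xyz, beads = beads,
                       config = list()), class = "cg_trajectory")
  expect_error(occupancy_density(tr, reference = "protein"), "degenerate")
})

test_that("bending angles follow the half-axis definition", {
  expect_lt(bending_angle(dna42())[1], 2)
  expect_lt(bending_angle(build_dna_cg(demo_sequence("polyAT42")))[1], 2)

  # hinged conformation with 60 degrees between half axes
  n <- 42
  u <- c(0, 0, 1)
  v <- c(sin(60 * pi / 180), 0, cos(60 * pi / 180))
  pts <- matrix(0, n, 3)
  for (i in 2:n) {
    d <- if (i <= n / 2) u else v
    pts[i, ] <- pts[i - 1, ] + 0.334 * d
  }
  fake <- list(beads = data.frame(index = 1:n, label = "AT", resno = 1:n,
                                  x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                  radius = 0.8, charge = 0, group = "bp"))
  class(fake) <- "cg_structure"
  expect_equal(bending_angle(fake)[1], 60, tolerance = 1)

  expect_error(bending_angle(build_dna_cg("ACGTACG")), ">= 8")
})

test_that("RMSF vanishes for rigidly translated frames and matches by hand", {
  nf <- 6
  base <- matrix(rnorm(12), 4, 3)
  xyz <- array(0, c(nf, 4, 3))
  set.seed(2)
  for (f in 1:nf)
    xyz[f, , ] <- sweep(base %*% t(test_rotation()), 2, rnorm(3) * 3, "+")
  beads <- data.frame(index = 1:4, label = "X", resno = 1:4, x = 0, y = 0,
                      z = 0, radius = 0.3, charge = 0, group = "bead",
                      molecule = "protein", mol = 1)
  tr <- structure(list(times = 1:nf, xyz = xyz, beads = beads,
                       config = list()), class = "cg_trajectory")
  expect_lt(max(rmsf(tr, align = TRUE)), 1e-8)

  # 3-frame toy input vs the definition computed by hand
  xyz2 <- array(0, c(3, 2, 3))
  xyz2[, 1, 1] <- c(0, 1, 2)
  xyz2[, 2, 2] <- c(0, 0, 3)
  tr2 <- structure(list(times = 1:3, xyz = xyz2,
                        beads = beads[1:2, ], config = list()),
                   class = "cg_trajectory")
  got <- rmsf(tr2, align = FALSE)
  hand <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(got[1], hand(c(0, 1, 2)), tolerance = 1e-12)
  expect_equal(got[2], hand(c(0, 0, 3)), tolerance = 1e-12)
  one_frame <- structure(list(times = 1, xyz = xyz2[1, , , drop = FALSE],
                              beads = beads[1:2, ], config = list()),
                         class = "cg_trajectory")
  expect_error(rmsf(one_frame), ">= 2")
})

test_that("KS resampling behaves at the null and at disjoint support", {
  set.seed(6)
  a <- rnorm(1500); b <- rnorm(1500)
  r <- ks_resample(a, b, 60, 60, rounds = 300, seed = 2)
  expect_gt(r$fraction_pass, 0.9)

  dis <- ks_resample(rnorm(200), rnorm(200) + 100, 60, 60, rounds = 50,
                     seed = 3)
  expect_equal(dis$fraction_pass, 0)

  const <- ks_resample(rep(1, 100), rep(1, 100), 60, 60, rounds = 20,
                       seed = 4)
  expect_equal(const$fraction_pass, 1)

  expect_error(ks_resample(rnorm(10), rnorm(10), 60, 5), "exceeds")
})

test_that("binding shifts DNA bending only moderately", {
  # Bound ensemble: in-contact frames of association runs with flexible DNA.
  # The compact mock protein induces a mild skew toward larger bending (the
  # DNA partially wraps a bundle smaller than the real domain), so the
  # check is for overlap and a bounded median shift rather than strict
  # statistical equivalence.
  a1 <- mock_a1(); dna <- dna42()
  bound <- c()
  for (s in 1:2) {
    set.seed(600 + s)
    d <- transform_cg(dna, cgbind:::random_rotation(), shift = -cgbind:::cog(dna))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    p <- transform_cg(a1, cgbind:::random_rotation(),
                      shift = 6 * dir - cgbind:::cog(a1))
    cfg <- sim_config(n_steps = 5e4, dt = 1e-3, save_stride = 400,
                      seed = 600 + s, rigid = c(FALSE, TRUE),
                      confine_radius = 22.5)
    tr <- simulate_cg(list(d, p), cfg)
    ip <- which(tr$beads$molecule == "protein")
    id <- which(tr$beads$molecule == "dna")
    ra <- tr$beads$radius[ip]; rb <- tr$beads$radius[id]
    ang <- as.numeric(bending_angle(tr))
    incontact <- vapply(seq_along(tr$times), function(f) {
      min(cgbind:::surface_dist(cgbind:::frame_coords(tr, f, ip),
                                cgbind:::frame_coords(tr, f, id),
                                ra, rb)) < 0.6
    }, logical(1))
    bound <- c(bound, ang[incontact])
  }
  unbound <- as.numeric(bending_angle(free_dna_run()))[-(1:400)]
  expect_lt(abs(median(bound) - median(unbound)), 10)
  r <- ks_resample(bound, unbound, nA = min(60, length(bound)), nB = 23,
                   rounds = 200, seed = 5)
  expect_gt(r$fraction_pass, 0.05)
})

test_that("CG runs from the docked pose bind through the arginine triad", {
  poses <- dock300()
  best <- pose_structure(poses, 1)
  cfg <- sim_config(n_steps = 4e4, dt = 1e-3, save_stride = 400, seed = 31,
                    rigid = c(TRUE, TRUE))
  tr <- simulate_cg(list(poses$dna, best), cfg)
  fr <- classify_regions(tr, region_map_a1())
  expect_equal(sum(fr), 1)
  expect_gt(fr[["region1"]], max(fr[c("region2", "both", "lysine_patch",
                                      "other", "none")]))
})
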