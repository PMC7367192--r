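test_that("docking returns the lowest-energy poses, ranked", {
  poses <- dock300()
  expect_equal(nrow(poses$data), 50)
  expect_true(all(diff(poses$data$total) >= 0))
  # every returned energy <= minimum among non-returned recorded poses
  others <- setdiff(poses$all_energies, poses$data$total)
  if (length(others))
    expect_lte(max(poses$data$total), min(others))
})

test_that("docking errors when no encounters are recorded", {
  cfg <- dock_config(n_runs = 5, n_select = 5, seed = 1, max_steps = 3)
  expect_error(bd_dock(mock_a1(), dna42(), 0.15, cfg), "encounter")
})

test_that("b-surface must exceed the molecular extent", {
  cfg <- dock_config(b_surface = 5, q_surface = 30)
  expect_error(bd_dock(mock_a1(), dna42(), 0.15, cfg), "extent")
})

test_that("rigid bodies stay rigid along BD trajectories", {
  a1 <- mock_a1(); dna <- dna42()
  cfg <- sim_config(n_steps = 2000, save_stride = 200, seed = 9,
                    rigid = c(TRUE, TRUE))
  tr <- simulate_cg(list(dna, a1), cfg)
  ip <- which(tr$beads$molecule == "protein")
  ref <- dist(matrix(tr$xyz[1, ip, ], ncol = 3))
  for (f in seq_along(tr$times)) {
    dd <- dist(matrix(tr$xyz[f, ip, ], ncol = 3))
    expect_lt(max(abs(dd - ref)), 1e-9)
  }
})

test_that("stored pose energies match independent recomputation", {
  poses <- dock300()
  for (i in c(1, 10, 25)) {
    e <- pose_energy(poses, i)
    expect_equal(e$total, poses$data$total[i], tolerance = 1e-8)
    expect_equal(e$coulomb, poses$data$coulomb[i], tolerance = 1e-8)
  }
})

# dock_poses object with hand-made transforms, reusing a real skeleton
synthetic_poses <- function(trans, R = NULL, energies = NULL) {
  sk <- dock300()
  n <- nrow(trans)
  sk$data <- data.frame(run = seq_len(n), coulomb = 0, short_range = 0,
                        total = energies %||% -seq_len(n),
                        cluster = NA_integer_)
  sk$pose_t <- trans
  sk$pose_R <- if (is.null(R))
    matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), n), n, 9, byrow = TRUE) else R
  sk
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clustering separates well-separated pose groups", {
  set.seed(2)
  centers <- matrix(rnorm(15) * 10, 5, 3)
  while (min(dist(centers)) < 6) centers <- matrix(rnorm(15) * 10, 5, 3)
  trans <- centers[rep(1:5, each = 6), ] + matrix(rnorm(90, sd = 0.1), 30, 3)
  poses <- synthetic_poses(trans)
  cl <- cluster_poses(poses, h = 1.0)
  expect_equal(length(unique(cl$data$cluster)), 5)
  reps <- attr(cl, "representatives")
  expect_equal(length(reps), 5)
  # one representative per planted group, each the lowest-energy member
  groups <- rep(1:5, each = 6)
  expect_setequal(groups[reps], 1:5)
  for (r in reps) {
    g <- groups[r]
    expect_equal(cl$data$total[r], min(cl$data$total[groups == g]))
  }
  # fixed-count mode
  cl5 <- cluster_poses(poses, k = 5)
  expect_equal(length(unique(cl5$data$cluster)), 5)
})

test_that("degenerate pose sets cluster trivially", {
  one <- synthetic_poses(matrix(c(1, 2, 3), 1, 3))
  c1 <- cluster_poses(one)
  expect_identical(attr(c1, "representatives"), 1L)

  same <- synthetic_poses(matrix(rep(c(1, 2, 3), 10), 10, 3, byrow = TRUE))
  cs <- cluster_poses(same, h = 1.0)
  expect_equal(length(unique(cs$data$cluster)), 1)
})

test_that("NAM reduces to the Smoluchowski rate for neutral touching spheres", {
  p <- bead_system(matrix(0, 1, 3), radius = 0.75)
  p$molecule <- "protein"
  d <- bead_system(matrix(0, 1, 3), radius = 0.75)
  d$molecule <- "dna"
  a_capture <- 1.5  # contact of the two spheres
  cfg <- dock_config(n_runs = 1500, n_select = 10, b_surface = 5,
                     q_surface = 20, reaction_contacts = 1,
                     reaction_distance = 1e-4, charged_contacts = FALSE,
                     seed = 31, max_steps = 400000,
                     hydro_radius_protein = 1.0)
  r <- estimate_kon_nam(p, d, 0.15, cfg)
  D_rel <- r$kD_b / (4 * pi * cfg$b_surface * 6.02214076e8)  # back out D
  kon_exact <- 4 * pi * D_rel * a_capture * 6.02214076e8
  se_rel <- sqrt((1 - r$beta) / (r$beta * cfg$n_runs))
  expect_lt(abs(r$kon - kon_exact) / kon_exact, 3.5 * se_rel)
  expect_true(r$kon > 0 && r$beta >= 0 && r$beta <= 1)
})

test_that("NAM confidence interval shrinks ~sqrt(2) when runs double", {
  p <- bead_system(matrix(0, 1, 3), radius = 0.75); p$molecule <- "protein"
  d <- bead_system(matrix(0, 1, 3), radius = 0.75); d$molecule <- "dna"
  base <- dock_config(n_runs = 800, n_select = 10, b_surface = 5,
                      q_surface = 20, reaction_contacts = 1,
                      reaction_distance = 1e-4, charged_contacts = FALSE,
                      seed = 77, max_steps = 400000,
                      hydro_radius_protein = 1.0)
  twice <- base; twice$n_runs <- 1600
  r1 <- estimate_kon_nam(p, d, 0.15, base)
  r2 <- estimate_kon_nam(p, d, 0.15, twice)
  ratio <- diff(r1$ci) / diff(r2$ci)
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.75)
})

test_that("attraction raises kon above the neutral rate", {
  p <- bead_system(matrix(0, 1, 3), radius = 0.75, charge = 4)
  p$molecule <- "protein"
  d <- bead_system(matrix(0, 1, 3), radius = 0.75, charge = -4)
  d$molecule <- "dna"
  cfg <- dock_config(n_runs = 600, n_select = 10, b_surface = 5,
                     q_surface = 20, reaction_contacts = 1,
                     reaction_distance = 1e-4, charged_contacts = FALSE,
                     seed = 41, max_steps = 400000,
                     hydro_radius_protein = 1.0)
  katt <- estimate_kon_nam(p, d, 0.05, cfg)$kon
  p0 <- p; p0$beads$charge <- 0
  kneu <- estimate_kon_nam(p0, d, 0.05, cfg)$kon
  expect_gt(katt, kneu)
})

test_that("a neutral protein docks with orientation-uniform poses", {
  a0 <- mock_a1()
  a0$beads$charge <- rep(0, nrow(a0$beads))
  cfg <- dock_config(n_runs = 250, n_select = 250, seed = 9,
                     max_steps = 60000)
  poses <- bd_dock(a0, dna42(), 0.15, cfg)
  # cos(angle between the protein body z-axis and the lab z-axis) must be
  # uniform on [-1, 1] for an orientation-uniform pose ensemble
  cosz <- poses$pose_R[, 9]
  set.seed(1)
  ks <- suppressWarnings(ks.test(cosz, runif(5000, -1, 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("salt scans weaken binding and shift the contact footprint", {
  sc <- salt_scan2()
  expect_lt(sc[[1]]$mean_energy, sc[[2]]$mean_energy)
  expect_gt(abs(sc[[1]]$mean_energy), abs(sc[[2]]$mean_energy))
  # per-residue contact footprint differs between 0.05 M and 1.0 M
  m <- merge(sc[[1]]$contact_fraction, sc[[2]]$contact_fraction, by = "resno")
  counts <- cbind(round(m$fraction.x * 150), round(m$fraction.y * 150))
  keep <- rowSums(counts) > 0
  p <- suppressWarnings(chisq.test(counts[keep, ]))$p.value
  expect_lt(p, 0.05)
})

test_that("a single-salt scan equals direct docking with the same seed", {
  cfg <- dock_config(n_runs = 60, n_select = 20, seed = 15,
                     max_steps = 100000)
  sc <- salt_scan(mock_a1(), dna42(), 0.15, cfg)
  direct <- bd_dock(mock_a1(), dna42(), 0.15, cfg)
  expect_identical(sc[[1]]$poses$data$total, direct$data$total)
  expect_identical(sc[[1]]$poses$pose_t, direct$pose_t)
})
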