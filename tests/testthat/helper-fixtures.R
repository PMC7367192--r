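# Shared fixtures.  Heavy simulation products are computed once per test run
# and reused across files (helpers are sourced once per session).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

mock_a1 <- function() cached("mock_a1", generate_mock_a1())
dna42 <- function() cached("dna42", build_dna_cg(demo_sequence("ds42")))

# ten alanine beads on a ring: outward normals are radial, so planted
# trajectories can touch one residue without touching its neighbours
ring_protein <- function(charges = NULL) {
  th <- seq(0, 2 * pi, length.out = 11)[1:10]
  resid <- rep("ALA", 10)
  if (!is.null(charges)) resid[charges] <- "ARG"
  build_protein_cg(cbind(6 * cos(th), 6 * sin(th), 0),
                   resno = 101:110, resid = resid)
}

# free 42-bp DNA equilibrium run (t3 protocol, shorter saves for reuse)
free_dna_run <- function() {
  cached("free_dna_run", {
    simulate_cg(dna42(),
                sim_config(n_steps = 1e6, dt = 1e-3, save_stride = 500,
                           seed = 42))
  })
}

# 42-replica association campaign at the reference-protocol run length
campaign210 <- function() {
  cached("campaign210", {
    run_association_campaign(mock_a1(), dna42(), n_replicas = 42,
                             separation = 6, t_max = 210, seed = 100)
  })
}

# moderate docking of the mock A1 against the 42-bp duplex
dock300 <- function() {
  cached("dock300", {
    bd_dock(mock_a1(), dna42(), 0.15,
            dock_config(n_runs = 300, n_select = 50, seed = 5))
  })
}

# salt scan reused by the docking tests and the acceptance suite
salt_scan2 <- function() {
  cached("salt_scan2", {
    salt_scan(mock_a1(), dna42(), c(0.05, 1.0),
              dock_config(n_runs = 500, n_select = 150, seed = 21))
  })
}

# build a minimal hand-made two-molecule trajectory (single-bead molecules)
toy_trajectory <- function(dists, dt_save = 0.01, radius = 0.2) {
  nf <- length(dists)
  xyz <- array(0, c(nf, 2, 3))
  xyz[, 2, 1] <- dists + 2 * radius  # centre distance giving surface dist
  beads <- data.frame(index = 1:2, label = c("A", "B"), resno = 1:2,
                      x = 0, y = 0, z = 0, radius = radius, charge = 0,
                      group = "bead", molecule = c("protein", "dna"),
                      mol = 1:2)
  structure(list(times = (seq_len(nf) - 1) * dt_save, xyz = xyz,
                 beads = beads, energies = NULL, first_contact = NA,
                 config = list(seed = 0, dt = dt_save),
                 provenance = "toy"),
            class = "cg_trajectory")
}

# random rotation matrix for tests, driven by the R RNG
test_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}
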