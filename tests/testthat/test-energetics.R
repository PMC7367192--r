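test_that("Debye length follows the ionic-strength formula", {
  expect_equal(debye_length(0.15, 298, 78.5), 0.785, tolerance = 0.01)
  expect_identical(debye_length(0), Inf)
  expect_equal(debye_length(0.6), debye_length(0.15) / 2, tolerance = 1e-12)
  expect_error(debye_length(-1), ">= 0")
})

test_that("screened pair energy has the Coulomb prefactor and limits", {
  p0 <- elec_params(ionic_strength = 0, temperature = 298.15, epsr = 78.5)
  expect_equal(dh_pair_energy(1, 1, 1, p0), 138.935458 / 78.5,
               tolerance = 1e-10)
  expect_identical(dh_pair_energy(1, 0, 0.7, p0), 0)
  ps <- elec_params(0.15, 298.15, 78.5)
  expect_lt(abs(dh_pair_energy(1, 1, 1, ps)), abs(dh_pair_energy(1, 1, 1, p0)))
  expect_error(dh_pair_energy(1, 1, 0, p0), "> 0")
  # -> 0 as r -> Inf
  expect_lt(abs(dh_pair_energy(1, 1, 500, p0)), 1e-2)
})

# same shifted/cutoff pair model as the engine, in plain R
naive_pair_sum <- function(a, b, params) {
  ba <- if (inherits(a, "cg_structure")) a$beads else a
  bb <- if (inherits(b, "cg_structure")) b$beads else b
  ec <- 0; es <- 0
  shift <- exp(-params$kappa * params$cutoff) / params$cutoff
  for (i in seq_len(nrow(ba))) {
    for (j in seq_len(nrow(bb))) {
      r <- sqrt((ba$x[i] - bb$x[j])^2 + (ba$y[i] - bb$y[j])^2 +
                  (ba$z[i] - bb$z[j])^2)
      if (ba$charge[i] != 0 && bb$charge[j] != 0 && r < params$cutoff)
        ec <- ec + params$coulomb_prefactor * ba$charge[i] * bb$charge[j] *
          (exp(-params$kappa * r) / r - shift)
      sigc <- ba$radius[i] + bb$radius[j]
      if (r < sigc) {
        sig <- sigc * 2^(-1 / 6)
        es <- es + 4 * params$wca_eps * ((sig / r)^12 - (sig / r)^6) +
          params$wca_eps
      }
    }
  }
  list(coulomb = ec, short_range = es)
}

test_that("interaction energy equals the brute-force pair sum", {
  params <- elec_params(0.15)
  # 3-bead vs 2-bead toy system: explicit 6-term sum
  a <- bead_system(rbind(c(0, 0, 0), c(1, 0.2, 0), c(0.5, 1, 0.3)),
                   radius = 0.3, charge = c(1, -1, 1))
  b <- bead_system(rbind(c(0.8, 0.8, 0.8), c(1.5, 0, 1)),
                   radius = c(0.3, 0.5), charge = c(-1, 0))
  got <- interaction_energy(a, b, params)
  ref <- naive_pair_sum(a, b, params)
  expect_equal(got$coulomb, ref$coulomb, tolerance = 1e-10)
  expect_equal(got$short_range, ref$short_range, tolerance = 1e-10)

  # property: random systems of up to 10 beads
  set.seed(11)
  for (rep in 1:5) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- bead_system(matrix(rnorm(3 * na, sd = 1.2), ncol = 3), radius = 0.3,
                     charge = sample(-1:1, na, replace = TRUE))
    b <- bead_system(matrix(rnorm(3 * nb, sd = 1.2) + 1, ncol = 3),
                     radius = 0.3,
                     charge = sample(-1:1, nb, replace = TRUE))
    got <- interaction_energy(a, b, params)
    ref <- naive_pair_sum(a, b, params)
    expect_equal(got$total, ref$coulomb + ref$short_range, tolerance = 1e-10)
  }
})

test_that("distant structures have vanishing interaction energy", {
  params <- elec_params(0.15)
  a <- bead_system(matrix(0, 1, 3), radius = 0.3, charge = 3)
  b <- bead_system(matrix(100 / params$kappa, 1, 3), radius = 0.3,
                   charge = -5)
  e <- interaction_energy(a, b, params)
  expect_lt(abs(e$coulomb) + abs(e$short_range), 1e-6)
  expect_identical(e$total, e$coulomb + e$short_range)
})

test_that("opposite net charges attract at moderate separation", {
  params <- elec_params(0.15)
  a <- bead_system(matrix(0, 1, 3), radius = 0.3, charge = 2)
  b <- bead_system(matrix(c(1.5, 0, 0), 1, 3), radius = 0.3, charge = -3)
  expect_lt(interaction_energy(a, b, params)$coulomb, 0)
})

test_that("screening is monotone in ionic strength", {
  a <- bead_system(rbind(c(0, 0, 0), c(0.9, 0, 0)), radius = 0.2,
                   charge = c(2, 1))
  b <- bead_system(rbind(c(2, 0.4, 0), c(2.5, -0.3, 0.2)), radius = 0.2,
                   charge = c(-1, -2))
  mags <- vapply(c(0.02, 0.05, 0.15, 0.5, 1),
                 function(I) abs(interaction_energy(a, b, elec_params(I))$coulomb),
                 numeric(1))
  expect_true(all(diff(mags) <= 0))
})

test_that("DNA internal energy is the quadratic step form", {
  params <- bp_step_params()
  expect_lt(abs(dna_internal_energy(dna42(), params)), 1e-9)

  dev <- matrix(0, 1, 6); dev[1, 2] <- 3  # 3 degrees of roll
  e1 <- dna_internal_energy(dev, params)
  dev2 <- dev; dev2[1, 2] <- 6
  expect_equal(dna_internal_energy(dev2, params), 4 * e1, tolerance = 1e-12)

  # hand-computed diagonal quadratic form
  K <- diag(params$stiffness)
  x <- c(1, -2, 0.5, 0.01, -0.02, 0.005)
  expect_equal(dna_internal_energy(matrix(x, 1, 6), params),
               0.5 * sum(K * x^2), tolerance = 1e-12)
  expect_error(dna_internal_energy(matrix(0, 1, 5), params), "6 columns")
})

test_that("step forces and torques match central finite differences", {
  set.seed(7)
  p <- cgbind:::step_params_engine(bp_step_params())
  o1 <- rnorm(3) * 0.1
  o2 <- o1 + c(0.05, 0.03, 0.32)
  R1 <- test_rotation()
  R2 <- test_rotation() %*% R1
  v1 <- as.vector(t(R1)); v2 <- as.vector(t(R2))
  ef <- cgbind:::cpp_step_ef(o1, v1, o2, v2, p$k6, p$twist0, p$rise0)
  h <- 1e-6
  en <- function(o1, R1, o2, R2)
    cgbind:::cpp_step_ef(o1, as.vector(t(R1)), o2, as.vector(t(R2)),
                         p$k6, p$twist0, p$rise0)$energy
  rot_exp <- function(w) {
    th <- sqrt(sum(w^2))
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
  }
  for (c_ in 1:3) {
    d <- numeric(3); d[c_] <- h
    expect_equal(ef$f2[c_], -(en(o1, R1, o2 + d, R2) - en(o1, R1, o2 - d, R2)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(ef$f1[c_], -(en(o1 + d, R1, o2, R2) - en(o1 - d, R1, o2, R2)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(ef$t1[c_],
                 -(en(o1, rot_exp(d) %*% R1, o2, R2) -
                     en(o1, rot_exp(-d) %*% R1, o2, R2)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(ef$t2[c_],
                 -(en(o1, R1, o2, rot_exp(d) %*% R2) -
                     en(o1, R1, o2, rot_exp(-d) %*% R2)) / (2 * h),
                 tolerance = 1e-6)
  }
})
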