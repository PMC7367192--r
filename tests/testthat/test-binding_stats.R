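test_that("the association-rate fit recovers synthetic kinetics", {
  # recovery within 5% of truth on average (single draws at n = 500 carry
  # ~4.5% sampling error, so the recovery claim is about the estimator mean)
  kons <- vapply(1:25, function(i) {
    di <- generate_datasets("event_times", n = 500, seed = 400 + i,
                            kon = 5.7e11, conc = 3.5e-5, t_max = Inf)
    fit_kon(di$data)$kon
  }, numeric(1))
  expect_equal(mean(kons), 5.7e11, tolerance = 0.05)
  d <- generate_datasets("event_times", n = 500, seed = 5, kon = 5.7e11,
                         conc = 3.5e-5, t_max = Inf)
  fit <- fit_kon(d$data)
  expect_equal(fit$kon, d$truth$kon, tolerance = 0.15)

  # rescaling all times by 2 halves kon exactly
  ev2 <- d$data
  ev2$times <- ev2$times * 2
  ev2$run_length <- ev2$run_length * 2
  expect_equal(fit_kon(ev2)$kon, fit$kon / 2, tolerance = 1e-9)

  # censored-exponential MLE agrees to sampling accuracy
  expect_equal(fit_kon(d$data, method = "mle")$kon, d$truth$kon,
               tolerance = 0.1)
})

test_that("the association-rate fit validates its inputs", {
  ev <- association_events(times = rep(5, 10), censored = rep(TRUE, 10),
                           conc = 1e-5, run_length = 5)
  expect_error(fit_kon(ev), "uncensored")
  ev2 <- association_events(times = 1:10, censored = rep(FALSE, 10),
                            conc = 0, run_length = 10)
  expect_error(fit_kon(ev2), "C")
  ev3 <- association_events(times = 1:3, censored = rep(FALSE, 3),
                            conc = 1e-5, run_length = 3)
  expect_error(fit_kon(ev3), "uncensored")
})

test_that("encounter time reduces to Smoluchowski and is monotone in charge", {
  p0 <- encounter_params(q1 = 0, q2 = 0, D_rel = 0.3, a = 2, conc = 1e-5)
  et <- encounter_time(p0)
  kon_exact <- 4 * pi * 0.3 * 2 * 6.02214076e8
  expect_equal(et$kon, kon_exact, tolerance = 1e-4)
  expect_equal(et$tau_ns, 1e9 / (kon_exact * 1e-5), tolerance = 1e-4)

  t_att <- encounter_time(encounter_params(q1 = 6, q2 = -82))$tau_ns
  t_neu <- encounter_time(encounter_params(q1 = 0, q2 = 0))$tau_ns
  t_rep <- encounter_time(encounter_params(q1 = 6, q2 = 82))$tau_ns
  expect_lt(t_att, t_neu)
  expect_gt(t_rep, t_neu)
})

# 1D radial walker with the 3D radial drift term, reflecting outer shell
mfpt_oracle <- function(pars, n_walkers = 1500, seed = 9) {
  el <- elec_params(if (pars$screened) pars$ionic_strength else 0,
                    pars$temperature, pars$epsr)
  R_out <- (3 / (4 * pi * pars$conc * 6.02214076e23 * 1e-24))^(1 / 3)
  D <- pars$D_rel
  pref <- el$coulomb_prefactor * pars$q1 * pars$q2 * el$beta
  set.seed(seed)
  r <- (runif(n_walkers) * (R_out^3 - pars$a^3) + pars$a^3)^(1 / 3)
  t <- numeric(n_walkers)
  act <- rep(TRUE, n_walkers)
  while (any(act)) {
    ra <- r[act]
    dt <- pmax(5e-5, pmin(0.25, 0.004 * (ra - pars$a)^2 / (2 * D)))
    # radial drift: force term + 2D/r entropic term
    f <- pref * exp(-el$kappa * ra) * (el$kappa * ra + 1) / ra^2  # -dU/dr * beta
    drift <- (D * f + 2 * D / ra) * dt
    ra <- ra + drift + sqrt(2 * D * dt) * rnorm(length(ra))
    ra[ra > R_out] <- 2 * R_out - ra[ra > R_out]
    t[act] <- t[act] + dt
    hit <- ra <= pars$a
    r[act] <- ra
    done <- which(act)[hit]
    act[done] <- FALSE
  }
  mean(t)
}

test_that("the encounter quadrature matches a brute-force MFPT walker", {
  # concentration chosen so the spherical cell radius is 10 nm (a/R = 1/40,
  # keeping the uniform-start correction to the dilute-limit rate small)
  # modest contact barriers/wells (|U(a)| of a couple of kT) keep both the
  # quadrature and the Euler-discretized walker in a feasible regime
  cc <- 3.9645e-4 / 2   # spherical cell radius ~12.6 nm (a/R = 0.024)
  sets <- list(
    encounter_params(q1 = 0, q2 = 0, D_rel = 0.3, a = 0.3, conc = cc),
    encounter_params(q1 = 1, q2 = -1, D_rel = 0.3, a = 0.3, conc = cc,
                     ionic_strength = 0.3),
    encounter_params(q1 = 1, q2 = 1, D_rel = 0.3, a = 0.3, conc = cc,
                     ionic_strength = 0.3))
  for (pars in sets) {
    tau <- encounter_time(pars)$tau_ns
    oracle <- mfpt_oracle(pars)
    expect_lt(abs(tau - oracle) / oracle, 0.10)
  }
})

test_that("isotherm fits recover ground truth and flag degenerate data", {
  d <- generate_datasets("isotherm", n = 12, noise = 0, Kd = 1e-5)
  fit <- fit_isotherm(d$data$conc, d$data$signal)
  expect_equal(fit$Kd, 1e-5, tolerance = 1e-6)
  expect_true(fit$converged && fit$saturating)

  # 5% noise, 12 points: median recovery within 15% over 100 repeats
  kds <- vapply(1:100, function(i) {
    di <- generate_datasets("isotherm", n = 12, noise = 0.05, Kd = 1e-5,
                            seed = 100 + i)
    fit_isotherm(di$data$conc, di$data$signal)$Kd
  }, numeric(1))
  expect_lt(abs(median(kds) - 1e-5) / 1e-5, 0.15)

  flat <- fit_isotherm(10^seq(-7, -3, length.out = 6), rep(1, 6))
  expect_false(flat$converged)

  # non-saturating titration flagged
  d2 <- generate_datasets("isotherm", n = 8, noise = 0, Kd = 1e-3,
                          conc_range = c(1e-7, 1e-5))
  f2 <- fit_isotherm(d2$data$conc, d2$data$signal)
  expect_false(f2$saturating)

  # Hill variant reduces to the same answer at n = 1
  fh <- fit_isotherm(d$data$conc, d$data$signal, model = "hill")
  expect_equal(fh$Kd, 1e-5, tolerance = 1e-3)
  expect_equal(fh$n, 1, tolerance = 1e-3)
})

test_that("counterion regression is exact least squares", {
  d <- generate_datasets("salt_series", n = 5, noise = 0, b = -6, a = -2)
  fit <- counterion_regression(d$data$salt, d$data$Kd)
  expect_equal(fit$b, -6, tolerance = 1e-10)
  expect_equal(fit$a, -2, tolerance = 1e-10)

  # two points: exact interpolating line
  f2 <- counterion_regression(c(0.02, 0.2), c(1e-8, 1e-5))
  expect_equal(f2$b, -3, tolerance = 1e-10)

  # hand least squares on an arbitrary 3-point input
  salt <- c(0.02, 0.05, 0.3); Kd <- c(3e-9, 8e-7, 2e-5)
  x <- log10(salt); y <- -log10(Kd)
  b_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hand <- mean(y) - b_hand * mean(x)
  f3 <- counterion_regression(salt, Kd)
  expect_equal(f3$b, b_hand, tolerance = 1e-10)
  expect_equal(f3$a, a_hand, tolerance = 1e-10)

  expect_error(counterion_regression(c(0.1, -0.2), c(1e-6, 1e-6)), "> 0")
  expect_error(counterion_regression(0.1, 1e-6), ">= 2")
})

test_that("two-component FCS fits recover the bound fraction", {
  d <- generate_datasets("fcs", n = 80, noise = 0, f = 0.25, tauD1 = 1e-4,
                         tauD2 = 1e-3)
  fit <- fit_fcs_two_component(d$data$lag, d$data$G, tauD1 = 1e-4)
  expect_equal(fit$f, 0.25, tolerance = 1e-5)
  expect_equal(fit$tauD2, 1e-3, tolerance = 1e-4)
  expect_true(fit$identifiable)

  # single species: f = 0 within its confidence interval
  d1 <- generate_datasets("fcs", n = 80, noise = 0.002, f = 0, seed = 3)
  f1 <- fit_fcs_two_component(d1$data$lag, d1$data$G, tauD1 = 1e-4)
  expect_lt(f1$f - 2 * f1$f_se, 0.02)

  # 2% noise: f recovered within +-0.05
  d2 <- generate_datasets("fcs", n = 80, noise = 0.02, f = 0.25,
                          tauD2 = 1e-3, seed = 8)
  f2 <- fit_fcs_two_component(d2$data$lag, d2$data$G, tauD1 = 1e-4)
  expect_lt(abs(f2$f - 0.25), 0.05)

  # scaling G changes only the amplitude 1/N, not f
  f3 <- fit_fcs_two_component(d$data$lag, 3 * d$data$G, tauD1 = 1e-4)
  expect_equal(f3$f, fit$f, tolerance = 1e-4)
  expect_equal(f3$N, fit$N / 3, tolerance = 1e-4)
})

test_that("dataset generators are seed-deterministic with correct moments", {
  d1 <- generate_datasets("event_times", n = 200, seed = 7, kon = 5.7e11,
                          conc = 3.5e-5)
  d2 <- generate_datasets("event_times", n = 200, seed = 7, kon = 5.7e11,
                          conc = 3.5e-5)
  expect_identical(d1$data$times, d2$data$times)
  rate <- d1$truth$rate
  se <- (1 / rate) / sqrt(200)
  expect_lt(abs(mean(d1$data$times) - 1 / rate), 3 * se)
})
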