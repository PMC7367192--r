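# Model fits and closed-form kinetics: first-order association fits,
# diffusion-limited encounter times, binding isotherms, counterion-
# condensation regression, and two-component FCS autocorrelation fits.

#' First-order association-rate fit
#'
#' Fits 1 - exp(-kon [C] t) to the cumulative association-event curve of a
#' campaign (empirical cumulative fraction of replicas that have formed their
#' first contact by time t, normalized by the total replica count including
#' censored runs).  A maximum-likelihood exponential alternative (censored
#' runs contribute their full run length) is also available.
#'
#' @param events an [association_events()] object, or a data frame with
#'   columns `time_ns` and `censored` plus arguments `conc`/`run_length`.
#' @param method `"nls"` (least squares on the cumulative curve, default) or
#'   `"mle"` (censored exponential maximum likelihood).
#' @param conc,run_length used when `events` is a plain data frame.
#' @return object of class `kinetics_fit`: `kon` (M^-1 s^-1), `rate`
#'   (kon [C], ns^-1), standard error, covariance and residuals.
#' @export
fit_kon <- function(events, method = c("nls", "mle"), conc = NULL,
                    run_length = NULL) {
  method <- match.arg(method)
  if (!inherits(events, "association_events")) {
    df <- as.data.frame(events)
    events <- association_events(df$time_ns, df$censored, conc = conc,
                                 run_length = run_length %||% max(df$time_ns))
  }
  C <- events$conc
  if (is.null(C) || is.na(C) || C <= 0) stop("[C] must be > 0")
  t_u <- sort(events$times[!events$censored])
  n_tot <- length(events$times)
  if (length(t_u) < 5) stop("need >= 5 uncensored association events")
  # censored-exponential MLE (also the nls start value)
  t_total <- sum(t_u) + sum(events$censored) * events$run_length
  rate_mle <- length(t_u) / t_total                     # ns^-1
  if (method == "mle") {
    rate <- rate_mle
    se_rate <- rate / sqrt(length(t_u))
    resid <- NULL
  } else {
    # empirical cumulative association curve on a uniform time grid
    t_end <- if (is.finite(events$run_length)) events$run_length else max(t_u)
    tg <- seq(0, t_end, length.out = 201)[-1]
    Fhat <- vapply(tg, function(t) sum(t_u <= t), numeric(1)) / n_tot
    fit <- minpack.lm::nlsLM(Fhat ~ 1 - exp(-r * tg),
                             start = list(r = rate_mle),
                             lower = 1e-12,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    rate <- coef(fit)[["r"]]
    se_rate <- sqrt(vcov(fit)[1, 1])
    resid <- residuals(fit)
  }
  kon_ns <- rate / C                                    # M^-1 ns^-1
  structure(list(kon = kon_ns * 1e9, kon_se = se_rate / C * 1e9,
                 rate = rate, rate_se = se_rate, conc = C,
                 method = method, residuals = resid,
                 n_events = length(t_u), n_total = n_tot),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Association fit (%s): kon = %.3g M^-1 s^-1 (se %.2g), [C] = %.3g M, %d/%d events\n",
              x$method, x$kon, x$kon_se, x$conc, x$n_events, x$n_total))
  invisible(x)
}

#' Encounter-time parameters
#'
#' Parameters of the diffusion-limited encounter-time estimate for two point
#' charges in an electrolyte.  The relative diffusion coefficient defaults to
#' the Stokes-Einstein sum for the two hydrodynamic radii.
#'
#' @param q1,q2 net charges, e.
#' @param radius1,radius2 hydrodynamic radii, nm.
#' @param a reaction (contact) distance, nm.
#' @param ionic_strength ionic strength, mol/L.
#' @param temperature temperature, K.
#' @param epsr relative permittivity.
#' @param conc molecular concentration, mol/L.
#' @param D_rel relative diffusion coefficient, nm^2/ns (overrides radii).
#' @param screened use the screened (Debye-Hueckel) potential?  `FALSE`
#'   evaluates the unscreened Coulomb (Debye) limit.
#' @param viscosity solvent viscosity, Pa s.
#' @return object of class `encounter_params`.
#' @export
encounter_params <- function(q1 = 6, q2 = -82, radius1 = 2.0, radius2 = 2.6,
                             a = 4.6, ionic_strength = 0.15,
                             temperature = 298.15, epsr = 78.5,
                             conc = 3.5e-5, D_rel = NULL, screened = TRUE,
                             viscosity = water_viscosity(temperature)) {
  stopifnot(a > 0, conc > 0)
  if (is.null(D_rel))
    D_rel <- stokes_einstein(radius1, temperature, viscosity)$Dt +
      stokes_einstein(radius2, temperature, viscosity)$Dt
  structure(list(q1 = q1, q2 = q2, D_rel = D_rel, a = a,
                 ionic_strength = ionic_strength, temperature = temperature,
                 epsr = epsr, conc = conc, screened = screened),
            class = "encounter_params")
}

#' Declared substitute for the point-charge encounter calculation
#'
#' Parameter set used for the +6e/-82e encounter-time estimate at a molecular
#' concentration of 3.5e-5 M: Stokes-Einstein radii of 2.0 and 2.6 nm at
#' physiological temperature (310.15 K, with the matching water viscosity and
#' permittivity) and the unscreened Coulomb (Debye) limit of the interaction
#' potential.  See the methods vignette for why the unscreened limit, not the
#' 0.15 M screened potential, reproduces the tens-of-nanoseconds encounter
#' scale.
#'
#' @return an [encounter_params()] object.
#' @export
encounter_params_s3 <- function() {
  encounter_params(q1 = 6, q2 = -82, radius1 = 2.0, radius2 = 2.6, a = 4.6,
                   ionic_strength = 0.15, temperature = 310.15,
                   epsr = water_permittivity(310.15), conc = 3.5e-5,
                   screened = FALSE)
}

#' Diffusion-limited encounter time
#'
#' Mean encounter time of two (point-like) charged species at concentration
#' C: the diffusion-controlled rate is k = 4 pi D_rel / Integral_a^Inf
#' exp(U(r)/kT) r^-2 dr with U the (optionally screened) Coulomb potential,
#' evaluated by numerical quadrature, and tau = 1/(k C).
#'
#' @param params an [encounter_params()] object.
#' @return object of class `encounter_estimate`: `tau_ns`, `kon`
#'   (M^-1 s^-1), `k_nm3ns`, and the parameters.
#' @examples
#' # neutral Smoluchowski limit: tau = 1/(4 pi D a C N_A)
#' encounter_time(encounter_params(q1 = 0, q2 = 0))
#' @export
encounter_time <- function(params = encounter_params()) {
  stopifnot(inherits(params, "encounter_params"))
  el <- elec_params(if (params$screened) params$ionic_strength else 0,
                    params$temperature, params$epsr)
  k <- sd_rate(params$q1, params$q2, params$D_rel, params$a, el)
  if (!is.finite(k) || k <= 0)
    stop("quadrature failure: encounter rate not finite ",
         "(repulsive barrier too steep?)")
  kon <- k * .RATE_NM3NS_TO_MS
  tau <- 1e9 / (kon * params$conc)
  structure(list(tau_ns = tau, kon = kon, k_nm3ns = k, params = params),
            class = "encounter_estimate")
}

#' @export
print.encounter_estimate <- function(x, ...) {
  cat(sprintf("Encounter estimate: tau = %.3g ns (kon = %.3g M^-1 s^-1) at [C] = %.3g M\n",
              x$tau_ns, x$kon, x$params$conc))
  invisible(x)
}

#' Binding-isotherm fit
#'
#' Weighted nonlinear least-squares fit of a titration curve with the general
#' 1:1 binding isotherm y = offset + amplitude * c/(c + Kd), or its Hill
#' generalization y = offset + amplitude * c^n/(c^n + Kd^n).
#'
#' @param conc ligand concentrations (mol/L, strictly positive, sorted).
#' @param signal measured signal (e.g. normalized fluorescence change).
#' @param err optional per-point standard errors (weights 1/err^2).
#' @param model `"one_site"` or `"hill"`.
#' @return object of class `isotherm_fit`: `Kd` with standard error and 95%
#'   CI, `amplitude`, `offset`, optional `n`, covariance, and flags
#'   `converged` and `saturating`.
#' @export
fit_isotherm <- function(conc, signal, err = NULL,
                         model = c("one_site", "hill")) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(signal))
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(conc) < 4) stop("need >= 4 titration points")
  w <- if (is.null(err)) rep(1, length(conc)) else 1 / err^2
  if (diff(range(signal)) == 0) {
    return(structure(list(Kd = NA_real_, Kd_se = NA_real_, ci = c(NA, NA),
                          amplitude = 0, offset = signal[1],
                          converged = FALSE, saturating = FALSE,
                          model = model),
                     class = "isotherm_fit"))
  }
  off0 <- min(signal); amp0 <- diff(range(signal))
  half <- off0 + amp0 / 2
  kd0 <- conc[which.min(abs(signal - half))]
  fml <- if (model == "one_site")
    signal ~ off + amp * conc / (conc + kd)
  else
    signal ~ off + amp * conc^n / (conc^n + kd^n)
  start <- list(off = off0, amp = amp0, kd = kd0)
  lower <- c(-Inf, -Inf, .Machine$double.xmin)
  if (model == "hill") { start$n <- 1; lower <- c(lower, 0.1) }
  fit <- try(minpack.lm::nlsLM(fml, start = start, weights = w,
                               lower = lower,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(Kd = NA_real_, Kd_se = NA_real_, ci = c(NA, NA),
                          converged = FALSE, saturating = FALSE,
                          model = model),
                     class = "isotherm_fit"))
  }
  cf <- coef(fit)
  vc <- try(vcov(fit), silent = TRUE)
  se <- if (inherits(vc, "try-error")) NA_real_ else sqrt(vc["kd", "kd"])
  saturating <- max(conc) > 2 * cf[["kd"]]
  structure(list(Kd = cf[["kd"]], Kd_se = se,
                 ci = cf[["kd"]] + c(-1.96, 1.96) * se,
                 amplitude = cf[["amp"]], offset = cf[["off"]],
                 n = if (model == "hill") cf[["n"]] else NULL,
                 cov = if (!inherits(vc, "try-error")) vc else NULL,
                 converged = TRUE, saturating = saturating, model = model,
                 fit = fit),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Isotherm fit: FAILED (flat or non-fittable data)\n")
    return(invisible(x))
  }
  cat(sprintf("Isotherm fit (%s): Kd = %.4g (se %.2g)%s\n", x$model, x$Kd,
              x$Kd_se,
              if (!x$saturating) " [non-saturating data: unbounded CI]" else ""))
  invisible(x)
}

#' Counterion-condensation salt regression
#'
#' Ordinary (optionally weighted) least squares of log10(Ka) on log10(salt),
#' Ka = 1/Kd.  In the counterion-condensation picture the slope `b`
#' estimates the number of counterions released upon binding, and the
#' intercept `a` the salt-independent component.
#'
#' @param salt salt concentrations, mol/L.
#' @param Kd dissociation constants, mol/L.
#' @param weights optional regression weights.
#' @return object of class `salt_regression`: `b`, `a`, standard errors and
#'   the `lm` fit.
#' @export
counterion_regression <- function(salt, Kd, weights = NULL) {
  stopifnot(length(salt) == length(Kd))
  if (length(salt) < 2) stop("need >= 2 (salt, Kd) pairs")
  if (any(salt <= 0) || any(Kd <= 0)) stop("salt and Kd must be > 0")
  x <- log10(salt); y <- -log10(Kd)
  fit <- if (is.null(weights)) lm(y ~ x) else lm(y ~ x, weights = weights)
  cf <- coef(fit)
  se <- if (length(x) > 2)
    suppressWarnings(sqrt(diag(vcov(fit)))) else c(NA_real_, NA_real_)
  structure(list(b = unname(cf[2]), a = unname(cf[1]),
                 b_se = unname(se[2]), a_se = unname(se[1]), fit = fit),
            class = "salt_regression")
}

#' @export
print.salt_regression <- function(x, ...) {
  cat(sprintf("log10(Ka) = %.3g * log10(salt) + %.3g  (slope se %.2g)\n",
              x$b, x$a, x$b_se))
  invisible(x)
}

# single-species 3D-Gaussian-volume FCS decay
fcs_g1 <- function(tau, tauD, s) {
  1 / ((1 + tau / tauD) * sqrt(1 + tau / (s^2 * tauD)))
}

#' Two-component FCS autocorrelation fit
#'
#' Fits G(tau) = (1/N) [(1 - f) g(tau; tauD1) + f g(tau; tauD2)] with g the
#' 3D-Gaussian-volume single-species decay, tauD1 (free species) and the
#' focal aspect ratio s held fixed; the bound fraction f is constrained to
#' [0, 1].
#'
#' @param lag lag times (s).
#' @param G autocorrelation values.
#' @param tauD1 fixed fast (free-species) diffusion time (s).
#' @param s fixed focal-volume aspect ratio.
#' @return object of class `fcs_fit`: `f` (bound fraction) with standard
#'   error, `tauD2`, `N`, and an `identifiable` flag (FALSE if the fitted
#'   tauD2 <= tauD1).
#' @export
fit_fcs_two_component <- function(lag, G, tauD1, s = 5) {
  stopifnot(length(lag) == length(G))
  if (min(lag) > tauD1 || max(lag) < tauD1)
    stop("lag range must cover the fixed diffusion time tauD1")
  n0 <- 1 / max(G)
  fit <- minpack.lm::nlsLM(
    G ~ (1 / N) * ((1 - f) * fcs_g1(lag, tauD1, s) + f * fcs_g1(lag, tD2, s)),
    start = list(N = n0, f = 0.2, tD2 = 20 * tauD1),
    lower = c(N = 1e-12, f = 0, tD2 = tauD1 * 1e-3),
    upper = c(N = Inf, f = 1, tD2 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  identifiable <- cf[["tD2"]] > tauD1
  if (!identifiable)
    warning("fitted tauD2 <= tauD1: two-component model unidentifiable")
  structure(list(f = cf[["f"]], f_se = unname(se["f"]),
                 tauD2 = cf[["tD2"]], N = cf[["N"]], tauD1 = tauD1, s = s,
                 identifiable = identifiable, fit = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("Two-component FCS fit: bound fraction f = %.3f (se %.3f), tauD2 = %.3g s%s\n",
              x$f, x$f_se, x$tauD2,
              if (!x$identifiable) " [UNIDENTIFIABLE]" else ""))
  invisible(x)
}
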