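# Independent numerical oracles used to validate the analytic and
# linearized computations, plus small fixture builders. The oracles never
# share code with the implementation paths they check.

# Two-state absorption model integrated numerically (deSolve::lsoda):
# gut amount a' = -ka a, central amount c' = ka a - ke c; bolus doses enter
# the gut as events. Returns concentrations in ng/ml at `times`.
ode_concentration <- function(cl, v, ka, dose_times, dose_amounts, times) {
  ke <- cl / v
  deriv <- function(t, y, parms)
    list(c(-ka * y[1], ka * y[1] - ke * y[2]))
  ev <- data.frame(var = "a", time = dose_times, value = dose_amounts,
                   method = "add")
  t_all <- sort(unique(c(0, dose_times, times)))
  out <- deSolve::lsoda(c(a = 0, c = 0), t_all, deriv, parms = NULL,
                        events = list(data = ev),
                        rtol = 1e-11, atol = 1e-14)
  conc <- out[match(times, out[, "time"]), "c"] / v * 1000
  unname(conc)
}

# -2 log marginal likelihood by adaptive quadrature over eta, per subject,
# excluding the n log(2*pi) constant so it is directly comparable with the
# default FOCE objective convention.
quadrature_ofv <- function(spec, dataset) {
  total <- 0
  n_tot <- 0
  for (s in dataset$subjects) {
    obs <- s$observations[!s$observations$bql, , drop = FALSE]
    if (nrow(obs) == 0) next
    lik <- function(eta_vec) vapply(eta_vec, function(eta) {
      f <- predict_individual(spec, s, eta = eta, times = obs$time)
      prod(stats::dnorm(obs$conc, f, spec$sigma_add)) *
        stats::dnorm(eta, 0, spec$omega_cl)
    }, numeric(1))
    marg <- stats::integrate(lik, -8 * spec$omega_cl, 8 * spec$omega_cl,
                             rel.tol = 1e-10)$value
    total <- total - 2 * log(marg)
    n_tot <- n_tot + nrow(obs)
  }
  total - n_tot * log(2 * pi)
}

# A small deterministic subject: q12h dosing, given observation times.
make_subject <- function(id = "S1", weight = 20, dose = 0.5,
                         obs_times = c(12, 24, 48), conc = NULL,
                         n_dose_days = 4) {
  doses <- dose_record(time = seq(0, n_dose_days * 24 - 12, by = 12),
                       amount = dose)
  if (is.null(conc)) conc <- rep(10, length(obs_times))
  pk_subject(id, weight, doses, observation_record(obs_times, conc))
}

# Subject whose observations sit exactly on the population prediction.
make_on_prediction_subject <- function(spec, id = "S1", weight = 20,
                                       dose = 0.5,
                                       obs_times = c(12, 24, 48)) {
  s <- make_subject(id, weight, dose, obs_times)
  s$observations$conc <- predict_individual(spec, s, eta = 0,
                                            times = obs_times)
  s
}

random_params <- function() {
  structural_params(cl = runif(1, 0.5, 20), v = runif(1, 10, 500),
                    ka = runif(1, 0.1, 2))
}
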