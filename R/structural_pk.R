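# One-compartment, first-order absorption, first-order elimination oral
# model. Internal units mg and L give mg/L; outputs are scaled x1000 to
# ng/ml, the unit of the 5-15 ng/ml therapeutic window. Bioavailability F is
# folded into the apparent parameters CL/F and V/F throughout.

#' Structural PK parameters
#'
#' @param cl Apparent oral clearance CL/F, L/h.
#' @param v Apparent volume of distribution V/F, L.
#' @param ka First-order absorption rate constant, 1/h.
#' @return Object of class `structural_params`.
#' @export
structural_params <- function(cl, v, ka) {
  if (!all(is.finite(c(cl, v, ka))) || cl <= 0 || v <= 0 || ka <= 0)
    stop("cl, v and ka must all be positive and finite")
  structure(list(cl = cl, v = v, ka = ka), class = "structural_params")
}

#' Dose regimen for repeated oral administration
#'
#' @param dose Dose per administration, mg (>= 0).
#' @param interval Dosing interval, hours (> 0).
#' @param n_doses Number of administrations; `Inf` marks steady state.
#' @return Object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose, interval = 12, n_doses = Inf) {
  if (dose < 0 || interval <= 0 || n_doses < 1)
    stop("invalid regimen: need dose >= 0, interval > 0, n_doses >= 1")
  structure(list(dose = dose, interval = interval, n_doses = n_doses),
            class = "dose_regimen")
}

# Bateman kernel: concentration (mg/L) at lag t >= 0 after a unit 1 mg dose.
# The ka == ke flip-flop degeneracy is resolved by the analytic limit
# t * ka * exp(-ka t) / v rather than division by (ka - ke).
bateman_unit <- function(t, cl, v, ka, tol = 1e-10) {
  ke <- cl / v
  out <- numeric(length(t))
  pos <- t >= 0
  if (abs(ka - ke) < tol * max(ka, ke)) {
    out[pos] <- ka * t[pos] * exp(-ka * t[pos]) / v
  } else {
    out[pos] <- ka / (v * (ka - ke)) * (exp(-ke * t[pos]) - exp(-ka * t[pos]))
  }
  out
}

#' Concentration after a single oral dose
#'
#' Analytic Bateman solution of the one-compartment model with first-order
#' absorption, in ng/ml. Returns 0 at `t = 0` (no drug absorbed yet).
#'
#' @param p [structural_params()].
#' @param dose Dose, mg.
#' @param t Time since the dose, hours (vectorized; must be >= 0).
#' @return Concentration(s), ng/ml.
#' @export
concentration_single_dose <- function(p, dose, t) {
  stopifnot(inherits(p, "structural_params"), all(t >= 0))
  1000 * dose * bateman_unit(t, p$cl, p$v, p$ka)
}

#' Concentration profile under repeated dosing by superposition
#'
#' Superposes single-dose solutions over every administration at or before
#' each requested time. Doses are given at `0, interval, ...` up to
#' `n_doses` administrations (capped at the last dose time not after
#' `max(times)`).
#'
#' @param p [structural_params()].
#' @param regimen [dose_regimen()] (finite `n_doses` or large horizon).
#' @param times Evaluation times, hours since the first dose.
#' @return Concentrations, ng/ml, one per time.
#' @export
concentration_profile <- function(p, regimen, times) {
  stopifnot(inherits(p, "structural_params"), all(times >= 0))
  n_eff <- min(regimen$n_doses, floor(max(times) / regimen$interval) + 1)
  dose_times <- (seq_len(n_eff) - 1) * regimen$interval
  lags <- outer(times, dose_times, "-")
  u <- bateman_unit(pmax(lags, 0), p$cl, p$v, p$ka)
  u[lags < 0] <- 0
  dim(u) <- dim(lags)
  1000 * regimen$dose * rowSums(u)
}

#' Steady-state trough concentration under repeated dosing
#'
#' Closed-form accumulation limit of the superposition series, evaluated at
#' the pre-dose time (one interval after a dose):
#' `D*ka/(v*(ka-ke)) * [exp(-ke*tau)/(1-exp(-ke*tau)) -
#'  exp(-ka*tau)/(1-exp(-ka*tau))]`, in ng/ml.
#'
#' @param p [structural_params()].
#' @param regimen [dose_regimen()]; only `dose` and `interval` are used.
#' @return Steady-state trough, ng/ml.
#' @export
steady_state_trough <- function(p, regimen) {
  stopifnot(inherits(p, "structural_params"))
  steady_state_trough_num(regimen$dose, p$cl, p$v, p$ka, regimen$interval)
}

# Numeric core, vectorized over cl (used heavily by the Monte Carlo engine).
steady_state_trough_num <- function(dose, cl, v, ka, tau, tol = 1e-10) {
  ke <- cl / v
  acc <- function(k) exp(-k * tau) / (1 - exp(-k * tau))
  degen <- abs(ka - ke) < tol * pmax(ka, ke)
  out <- 1000 * dose * ka / (v * (ka - ke)) * (acc(ke) - acc(ka))
  if (any(degen)) {
    # limit ke -> ka of the accumulation bracket over (ka - ke):
    # d/dk [exp(-k tau)/(1-exp(-k tau))] = -tau exp(-k tau)/(1-exp(-k tau))^2
    e <- exp(-ka * tau)
    out[degen] <- 1000 * dose * ka * tau * e / (v * (1 - e)^2)
  }
  out
}
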