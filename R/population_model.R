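# Fixed-effect covariate structure and stochastic components of the
# population model. Typical values scale allometrically with body weight
# relative to a 70 kg standard (exponent 0.75 for clearance, 1 for volume);
# inter-individual variability is lognormal on clearance; residual error is
# additive in ng/ml.

#' Allometric weight relation for a PK parameter
#'
#' `value(weight) = standard_value * (weight / standard_weight)^exponent`.
#'
#' @param standard_value Parameter value at the standard weight.
#' @param exponent Allometric exponent: 0.75 for flow-like parameters
#'   (clearance), 1 for size-like parameters (volume).
#' @param standard_weight Standard weight, kg (default 70).
#' @return Object of class `allometric_relation`.
#' @export
allometric_relation <- function(standard_value, exponent,
                                standard_weight = 70) {
  stopifnot(standard_value > 0, standard_weight > 0)
  structure(list(standard_value = standard_value, exponent = exponent,
                 standard_weight = standard_weight),
            class = "allometric_relation")
}

#' Covariate-parameter relation
#'
#' Power form, `TV * (cov / cov_median)^theta`, for continuous covariates;
#' categorical form, `TV * theta^cov` with `cov` in {0, 1}.
#'
#' @param covariate_name Covariate label matching the dataset's extra
#'   covariate names.
#' @param kind `"power"` or `"categorical"`.
#' @param theta Estimated coefficient.
#' @param covariate_median Population median (power kind only).
#' @param parameter Structural parameter the relation acts on, `"cl"` or
#'   `"v"`.
#' @return Object of class `covariate_relation`.
#' @export
covariate_relation <- function(covariate_name, kind = c("power", "categorical"),
                               theta = 0, covariate_median = NA_real_,
                               parameter = "cl") {
  kind <- match.arg(kind)
  if (!is.finite(theta)) stop("theta must be finite")
  if (kind == "power" && (!is.finite(covariate_median) ||
                          covariate_median <= 0))
    stop("power relation needs a positive covariate_median")
  stopifnot(parameter %in% c("cl", "v"))
  structure(list(covariate_name = covariate_name, kind = kind, theta = theta,
                 covariate_median = covariate_median, parameter = parameter),
            class = "covariate_relation")
}

#' Population model specification
#'
#' Bundles the allometric typical-value relations for CL/F and V/F, the
#' fixed absorption rate constant, optional covariate relations on the
#' typical values, the lognormal inter-individual variability of CL/F, and
#' the additive residual error.
#'
#' @param cl_std Typical CL/F at 70 kg, L/h.
#' @param v_std Typical V/F at 70 kg, L.
#' @param ka Absorption rate constant, 1/h (fixed; not estimated).
#' @param omega_cl Inter-individual variability of CL/F: the standard
#'   deviation of the log-scale random effect eta when `omega_is_sd` is
#'   TRUE (default), else its variance.
#' @param sigma_add Additive residual SD, ng/ml.
#' @param covariates List of included [covariate_relation()]s.
#' @param cl_exponent,v_exponent Allometric exponents.
#' @param omega_is_sd Interpretation switch for `omega_cl` (see Details).
#' @details Reported variability figures for this model are read as the
#'   log-scale SD (0.303 implies about a 31% coefficient of variation of
#'   clearance, typical for sirolimus); set `omega_is_sd = FALSE` to read
#'   the same number as a variance instead.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(cl_std, v_std, ka = 0.485, omega_cl = 0.303,
                       sigma_add = 3.578, covariates = list(),
                       cl_exponent = 0.75, v_exponent = 1,
                       omega_is_sd = TRUE) {
  stopifnot(ka > 0, omega_cl >= 0, sigma_add > 0)
  omega <- if (omega_is_sd) omega_cl else sqrt(omega_cl)
  structure(list(
    cl_allometry = allometric_relation(cl_std, cl_exponent),
    v_allometry = allometric_relation(v_std, v_exponent),
    ka = ka, omega_cl = omega, sigma_add = sigma_add,
    covariates = covariates), class = "model_spec")
}

#' The published final sirolimus model for pediatric lymphangioma
#'
#' Typical CL/F 11.3 L/h and V/F 388 L at 70 kg, allometric exponents
#' 0.75/1, Ka fixed at 0.485/h, lognormal inter-individual SD 0.303 on
#' CL/F, additive residual SD 3.578 ng/ml; weight is the only covariate
#' (via the allometry).
#'
#' @param omega_is_sd Interpret the 0.303 variability figure as the
#'   log-scale SD (default) or as a variance.
#' @return A [model_spec()].
#' @export
published_model <- function(omega_is_sd = TRUE) {
  model_spec(cl_std = 11.3, v_std = 388, ka = 0.485, omega_cl = 0.303,
             sigma_add = 3.578, omega_is_sd = omega_is_sd)
}

eval_allometry <- function(rel, weight) {
  rel$standard_value * (weight / rel$standard_weight)^rel$exponent
}

#' Apply a covariate relation to a typical parameter value
#'
#' @param base Positive typical value.
#' @param rel [covariate_relation()].
#' @param cov_value Subject's covariate value.
#' @return Adjusted positive value.
#' @export
apply_covariate <- function(base, rel, cov_value) {
  stopifnot(inherits(rel, "covariate_relation"))
  if (rel$kind == "power") {
    if (any(cov_value <= 0))
      stop("power covariate relation needs a positive covariate value")
    base * (cov_value / rel$covariate_median)^rel$theta
  } else {
    base * rel$theta^cov_value
  }
}

apply_covariates_for <- function(spec, parameter, base, covariates) {
  for (rel in spec$covariates) {
    if (rel$parameter != parameter) next
    cv <- covariates[[rel$covariate_name]]
    if (is.null(cv) || is.na(cv))
      stop("subject lacks covariate ", rel$covariate_name)
    base <- apply_covariate(base, rel, cv)
  }
  base
}

#' Typical apparent clearance at a body weight
#'
#' @param spec [model_spec()].
#' @param weight Body weight, kg (vectorized, positive).
#' @param covariates Optional named list of subject covariates, applied via
#'   the model's included covariate relations.
#' @return CL/F, L/h.
#' @export
typical_clearance <- function(spec, weight, covariates = list()) {
  if (any(weight <= 0)) stop("weight must be positive")
  apply_covariates_for(spec, "cl", eval_allometry(spec$cl_allometry, weight),
                       covariates)
}

#' Typical apparent volume of distribution at a body weight
#'
#' @inheritParams typical_clearance
#' @return V/F, L.
#' @export
typical_volume <- function(spec, weight, covariates = list()) {
  if (any(weight <= 0)) stop("weight must be positive")
  apply_covariates_for(spec, "v", eval_allometry(spec$v_allometry, weight),
                       covariates)
}

#' Individual parameter from a typical value and a log-scale random effect
#'
#' `M_i = TV(M) * exp(eta_i)`; with `eta ~ N(0, omega^2)` the individual
#' parameter is lognormal with median equal to the typical value.
#'
#' @param typical Positive typical value.
#' @param eta Log-scale deviation.
#' @return Positive individual value.
#' @export
individual_parameter <- function(typical, eta) {
  if (any(typical <= 0)) stop("typical value must be positive")
  typical * exp(eta)
}

#' Individual structural parameters for a subject
#'
#' @param spec [model_spec()].
#' @param subject [pk_subject()].
#' @param eta Log-scale clearance deviation (0 gives the population values).
#' @return [structural_params()].
#' @export
individual_params <- function(spec, subject, eta = 0) {
  cl <- individual_parameter(
    typical_clearance(spec, subject$weight, subject$covariates), eta)
  v <- typical_volume(spec, subject$weight, subject$covariates)
  structural_params(cl = cl, v = v, ka = spec$ka)
}

#' Predicted concentrations for one subject
#'
#' Builds the subject's individual parameters (clearance scaled by
#' `exp(eta)`, volume and Ka at their population values) and superposes the
#' subject's recorded dosing history at the requested times.
#'
#' @param spec [model_spec()].
#' @param subject [pk_subject()] with a nonempty dosing history.
#' @param eta Log-scale clearance deviation.
#' @param times Evaluation times, hours; defaults to the subject's
#'   observation times.
#' @return Concentrations, ng/ml.
#' @export
predict_individual <- function(spec, subject, eta = 0,
                               times = subject$observations$time) {
  if (nrow(subject$doses) == 0) stop("subject has no dosing history")
  p <- individual_params(spec, subject, eta)
  ev <- expand_doses(subject$doses)
  lags <- outer(times, ev$time, "-")
  u <- bateman_unit(pmax(lags, 0), p$cl, p$v, p$ka)
  u[lags < 0] <- 0
  dim(u) <- dim(lags)
  1000 * as.numeric(u %*% ev$amount)
}

# Expand dose rows carrying an interval (II > 0) into explicit events; a
# repeated-dose row covers administrations until the next dose row or, for
# the last row, a 4-week horizon beyond its start.
expand_doses <- function(doses, horizon = 28 * 24) {
  if (nrow(doses) == 0) return(data.frame(time = numeric(),
                                          amount = numeric()))
  times <- c(); amounts <- c()
  for (i in seq_len(nrow(doses))) {
    t0 <- doses$time[i]; ii <- doses$interval[i]
    if (ii <= 0) {
      times <- c(times, t0); amounts <- c(amounts, doses$amount[i])
    } else {
      t_end <- if (i < nrow(doses)) doses$time[i + 1] - 1e-9 else
        t0 + horizon
      reps <- seq(t0, t_end, by = ii)
      times <- c(times, reps)
      amounts <- c(amounts, rep(doses$amount[i], length(reps)))
    }
  }
  data.frame(time = times, amount = amounts)
}
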