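# First-order conditional estimation with interaction (FOCE-I) for the
# one-compartment allometric model with a single lognormal random effect on
# clearance and additive residual error. With a purely additive residual the
# interaction term is inert (the residual variance does not depend on eta),
# so FOCE-I coincides with FOCE here; the machinery is written against the
# general linearization and documented as such.
#
# Per-subject objective pieces use the rank-one structure of the conditional
# covariance C_i = G_i omega^2 G_i' + sigma^2 I (G_i = df_i/deta at the
# conditional mode): determinant and inverse come from the Sherman-Morrison
# identity, so no matrix factorizations are needed in the hot path.

#' Settings for the FOCE estimator
#'
#' @param inner_tolerance Convergence tolerance for the per-subject eta
#'   optimization (absolute step size on eta).
#' @param outer_tolerance Relative convergence tolerance for the fixed
#'   effects / variance components.
#' @param max_iterations Iteration caps, `c(inner, outer)`.
#' @param ofv_constant Whether the objective includes the `n log(2*pi)`
#'   constant. `"exclude"` (NONMEM convention, default) or `"include"`; the
#'   constant cancels in all objective-function differences.
#' @return Object of class `foce_settings`.
#' @export
foce_settings <- function(inner_tolerance = 1e-9, outer_tolerance = 1e-8,
                          max_iterations = c(inner = 50L, outer = 500L),
                          ofv_constant = c("exclude", "include")) {
  stopifnot(inner_tolerance > 0, outer_tolerance > 0)
  structure(list(inner_tolerance = inner_tolerance,
                 outer_tolerance = outer_tolerance,
                 max_iterations = max_iterations,
                 ofv_constant = match.arg(ofv_constant)),
            class = "foce_settings")
}

# Precompute everything eta-independent for one subject: non-BQL
# observations, expanded dosing events, lag matrix, and the absorption
# exponentials (Ka is fixed, so exp(-ka * lag) never changes).
subject_design <- function(subject, ka) {
  obs <- subject$observations[!subject$observations$bql, , drop = FALSE]
  ev <- expand_doses(subject$doses)
  lag <- outer(obs$time, ev$time, "-")
  mask <- lag >= 0
  lag[!mask] <- 0
  eka <- exp(-ka * lag)
  eka[!mask] <- 0
  list(y = obs$conc, times = obs$time, lag = lag, mask = mask, eka = eka,
       amt = ev$amount, n = nrow(obs), weight = subject$weight,
       covariates = subject$covariates, id = subject$subject_id)
}

dataset_designs <- function(dataset, ka) {
  lapply(dataset$subjects, subject_design, ka = ka)
}

# Predicted concentrations f (ng/ml) and df/deta for one subject at eta.
# cl0 is the subject's typical clearance; ke = cl0 exp(eta) / v.
conc_eta <- function(d, eta, cl0, v, ka) {
  ke <- cl0 * exp(eta) / v
  m <- exp(-ke * d$lag)
  m[!d$mask] <- 0
  base <- as.numeric((m - d$eka) %*% d$amt)
  k <- 1000 * ka / (v * (ka - ke))
  f <- k * base
  dbase_dke <- as.numeric(-(d$lag * m) %*% d$amt)
  df_dke <- k / (ka - ke) * base + k * dbase_dke
  list(f = f, g = df_dke * ke)
}

# Penalized conditional objective for eta and its analytic gradient:
#   q(eta) = sum (y - f(eta))^2 / sigma^2 + eta^2 / omega^2
inner_objective <- function(d, eta, cl0, v, ka, sigma2, omega2) {
  ce <- conc_eta(d, eta, cl0, v, ka)
  r <- d$y - ce$f
  list(value = sum(r^2) / sigma2 + eta^2 / omega2,
       grad = -2 * sum(r * ce$g) / sigma2 + 2 * eta / omega2,
       gn_hess = 2 * sum(ce$g^2) / sigma2 + 2 / omega2,
       f = ce$f, g = ce$g)
}

# Safeguarded Gauss-Newton/Newton search for the conditional mode, started
# at eta0 (warm starts across outer iterations), with step halving.
optimize_eta <- function(d, cl0, v, ka, sigma2, omega2, eta0 = 0,
                         tol = 1e-9, max_iter = 50L) {
  eta <- eta0
  cur <- inner_objective(d, eta, cl0, v, ka, sigma2, omega2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- -cur$grad / cur$gn_hess
    if (abs(step) < tol) { converged <- TRUE; break }
    step <- max(min(step, 2), -2)            # trust region on log scale
    lambda <- 1
    repeat {
      cand <- inner_objective(d, eta + lambda * step, cl0, v, ka,
                              sigma2, omega2)
      if (cand$value <= cur$value + 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (cand$value > cur$value) { converged <- TRUE; break }  # no descent
    eta <- eta + lambda * step
    cur <- cand
  }
  list(eta = eta, obj = cur, converged = converged || max_iter == 0L)
}

#' Conditional (empirical Bayes) eta for one subject
#'
#' Maximizes the joint density of the subject's data and random effect,
#' i.e. minimizes `sum((y - f(eta))^2)/sigma^2 + eta^2/omega^2`, by a
#' safeguarded Newton search started at 0. The curvature is the second
#' derivative of that objective at the mode (central finite difference of
#' the analytic gradient).
#'
#' @param spec [model_spec()] with `omega_cl > 0`.
#' @param subject [pk_subject()] with at least one usable observation.
#' @param settings [foce_settings()].
#' @return List with `eta_hat`, `curvature`, `converged`.
#' @export
conditional_eta <- function(spec, subject, settings = foce_settings()) {
  d <- subject_design(subject, spec$ka)
  if (d$n < 1) stop("subject ", subject$subject_id, " has no usable observations")
  if (spec$omega_cl <= 0) stop("conditional eta needs omega > 0")
  cl0 <- typical_clearance(spec, d$weight, d$covariates)
  v <- typical_volume(spec, d$weight, d$covariates)
  sigma2 <- spec$sigma_add^2
  omega2 <- spec$omega_cl^2
  res <- optimize_eta(d, cl0, v, spec$ka, sigma2, omega2,
                      tol = settings$inner_tolerance,
                      max_iter = settings$max_iterations[[1]])
  h <- 1e-5
  gp <- inner_objective(d, res$eta + h, cl0, v, spec$ka, sigma2, omega2)$grad
  gm <- inner_objective(d, res$eta - h, cl0, v, spec$ka, sigma2, omega2)$grad
  list(eta_hat = res$eta, curvature = (gp - gm) / (2 * h),
       converged = res$converged)
}

# Per-subject OFV contribution under the FOCE linearization at eta_hat.
# C = sigma^2 I + omega^2 g g'; r = y - f(eta_hat) + g * eta_hat.
#   log det C = n log sigma^2 + log(1 + omega^2 g'g / sigma^2)
#   r' C^-1 r = (r'r - omega^2 (g'r)^2 / (sigma^2 + omega^2 g'g)) / sigma^2
subject_ofv <- function(d, cl0, v, ka, sigma2, omega2, eta_state, idx,
                        tol, max_iter) {
  if (omega2 <= 0) {
    f <- conc_eta(d, 0, cl0, v, ka)$f
    r <- d$y - f
    return(list(ofv = d$n * log(sigma2) + sum(r^2) / sigma2, eta = 0))
  }
  res <- optimize_eta(d, cl0, v, ka, sigma2, omega2,
                      eta0 = eta_state$eta[idx], tol = tol,
                      max_iter = max_iter)
  eta_state$eta[idx] <- res$eta
  f <- res$obj$f; g <- res$obj$g
  r <- d$y - f + g * res$eta
  gtg <- sum(g^2); gtr <- sum(g * r)
  denom <- sigma2 + omega2 * gtg
  logdet <- d$n * log(sigma2) + log1p(omega2 * gtg / sigma2)
  quad <- (sum(r^2) - omega2 * gtr^2 / denom) / sigma2
  if (!is.finite(logdet + quad))
    stop("singular conditional covariance for subject ", d$id)
  list(ofv = logdet + quad, eta = res$eta, f = f, g = g)
}

ofv_from_designs <- function(designs, spec, sigma2, omega2, eta_state,
                             settings, keep_parts = FALSE) {
  ofv <- 0; n_tot <- 0
  parts <- if (keep_parts) vector("list", length(designs)) else NULL
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    if (d$n == 0) next
    cl0 <- typical_clearance(spec, d$weight, d$covariates)
    v <- typical_volume(spec, d$weight, d$covariates)
    part <- subject_ofv(d, cl0, v, spec$ka, sigma2, omega2, eta_state, i,
                        settings$inner_tolerance,
                        settings$max_iterations[[1]])
    ofv <- ofv + part$ofv
    n_tot <- n_tot + d$n
    if (keep_parts) parts[[i]] <- part
  }
  if (settings$ofv_constant == "include") ofv <- ofv + n_tot * log(2 * pi)
  list(ofv = ofv, parts = parts, n_obs = n_tot)
}

#' FOCE objective function value for a dataset
#'
#' Sum over subjects of `log det(C_i) + r_i' C_i^-1 r_i` under the
#' first-order conditional linearization at each subject's empirical Bayes
#' eta, with `C_i = G_i omega^2 G_i' + sigma^2 I` and
#' `r_i = y_i - f_i(eta_hat_i) + G_i eta_hat_i`. The `n log(2*pi)` constant
#' is excluded by default (NONMEM convention; it cancels in all
#' objective-function differences).
#'
#' @param spec [model_spec()].
#' @param dataset [pk_dataset()].
#' @param settings [foce_settings()].
#' @return Objective function value (scalar).
#' @export
foce_objective <- function(spec, dataset, settings = foce_settings()) {
  designs <- dataset_designs(dataset, spec$ka)
  eta_state <- new.env(parent = emptyenv())
  eta_state$eta <- numeric(length(designs))
  ofv_from_designs(designs, spec, spec$sigma_add^2, spec$omega_cl^2,
                   eta_state, settings)$ofv
}

# Rebuild a model_spec from the optimizer's working parameters.
# theta layout: log(cl_std), log(v_std), [covariate thetas...],
# log(omega), log(sigma). Power-relation thetas are unconstrained;
# categorical thetas are estimated on the log scale (multiplier > 0).
spec_from_par <- function(par, template) {
  ncov <- length(template$covariates)
  covs <- template$covariates
  if (ncov > 0) {
    for (j in seq_len(ncov)) {
      raw <- par[2 + j]
      covs[[j]]$theta <- if (covs[[j]]$kind == "categorical") exp(raw) else raw
    }
  }
  spec <- template
  spec$cl_allometry$standard_value <- exp(par[1])
  spec$v_allometry$standard_value <- exp(par[2])
  spec$covariates <- covs
  spec$omega_cl <- exp(par[2 + ncov + 1])
  spec$sigma_add <- exp(par[2 + ncov + 2])
  spec
}

par_from_spec <- function(spec) {
  ncov <- length(spec$covariates)
  covpar <- if (ncov > 0) vapply(spec$covariates, function(rel)
    if (rel$kind == "categorical") log(max(rel$theta, 1e-6)) else rel$theta,
    numeric(1)) else numeric(0)
  c(log(spec$cl_allometry$standard_value),
    log(spec$v_allometry$standard_value), covpar,
    log(max(spec$omega_cl, 1e-3)), log(spec$sigma_add))
}

par_names_from_spec <- function(spec) {
  covnames <- if (length(spec$covariates) > 0)
    paste0("theta_", vapply(spec$covariates, `[[`, "", "covariate_name"))
  else character(0)
  c("cl_std", "v_std", covnames, "omega_cl", "sigma_add")
}

#' Fit the population model by FOCE
#'
#' Estimates the typical CL/F and V/F at standard weight, any covariate
#' coefficients carried by `spec$covariates`, the inter-individual SD of
#' clearance and the additive residual SD, by minimizing the FOCE objective.
#' Ka stays fixed at `spec$ka`. Standard errors come from the
#' finite-difference Hessian of the objective at the optimum (relative step
#' 1e-4) and are reported as relative SE percentages.
#'
#' @param spec Starting [model_spec()] (also defines which covariate
#'   relations are estimated).
#' @param dataset [pk_dataset()] with at least two subjects carrying
#'   observations.
#' @param settings [foce_settings()].
#' @param compute_se Compute the Hessian-based relative standard errors
#'   (adds a Hessian's worth of objective evaluations).
#' @return Object of class `fit_result`: fitted `spec`, named `estimates`,
#'   `rse` (percent), `ofv`, per-subject `eta_hat`, `converged`, `n_obs`.
#' @export
fit_model <- function(spec, dataset, settings = foce_settings(),
                      compute_se = TRUE) {
  designs <- dataset_designs(dataset, spec$ka)
  usable <- sum(vapply(designs, function(d) d$n > 0, logical(1)))
  if (usable < 2) stop("need at least two subjects with usable observations")
  eta_state <- new.env(parent = emptyenv())
  eta_state$eta <- numeric(length(designs))
  objective <- function(par) {
    sp <- spec_from_par(par, spec)
    val <- try(ofv_from_designs(designs, sp, sp$sigma_add^2, sp$omega_cl^2,
                                eta_state, settings)$ofv, silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e10)
    val
  }
  start <- par_from_spec(spec)
  opt <- stats::nlminb(start, objective,
                       control = list(rel.tol = settings$outer_tolerance,
                                      iter.max = settings$max_iterations[[2]],
                                      eval.max = 4 * settings$max_iterations[[2]]))
  fitted_spec <- spec_from_par(opt$par, spec)
  final <- ofv_from_designs(designs, fitted_spec, fitted_spec$sigma_add^2,
                            fitted_spec$omega_cl^2, eta_state, settings,
                            keep_parts = TRUE)
  nm <- par_names_from_spec(spec)
  estimates <- c(fitted_spec$cl_allometry$standard_value,
                 fitted_spec$v_allometry$standard_value,
                 if (length(spec$covariates) > 0)
                   vapply(fitted_spec$covariates, `[[`, numeric(1), "theta"),
                 fitted_spec$omega_cl, fitted_spec$sigma_add)
  names(estimates) <- nm
  rse <- NULL
  if (compute_se) {
    log_scale <- c(TRUE, TRUE,
                   if (length(spec$covariates) > 0)
                     vapply(spec$covariates, function(rel)
                       rel$kind == "categorical", logical(1)),
                   TRUE, TRUE)
    rse <- tryCatch(rse_from_hessian(objective, opt$par, estimates,
                                     log_scale),
                    error = function(e) rep(NA_real_, length(estimates)))
    names(rse) <- nm
  }
  eta_hat <- vapply(seq_along(designs), function(i)
    if (designs[[i]]$n > 0) final$parts[[i]]$eta else NA_real_, numeric(1))
  names(eta_hat) <- vapply(dataset$subjects, `[[`, "", "subject_id")
  structure(list(spec = fitted_spec, estimates = estimates, rse = rse,
                 ofv = final$ofv, eta_hat = eta_hat,
                 converged = opt$convergence == 0, n_obs = final$n_obs,
                 settings = settings, optimizer = opt),
            class = "fit_result")
}

# RSE% via the finite-difference Hessian of the OFV in the working
# (log/identity) parameterization, delta-method-corrected to the natural
# scale. For -2 log L the covariance is 2 * H^-1.
rse_from_hessian <- function(objective, par, estimates, log_scale) {
  k <- length(par)
  h <- pmax(abs(par), 1) * 1e-4
  H <- matrix(0, k, k)
  f0 <- objective(par)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    fp[i] <- objective(par + ei); fm[i] <- objective(par - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    ei <- numeric(k); ei[i] <- h[i]
    ej <- numeric(k); ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (objective(par + ei + ej) - fp[i] - fp[j] + f0 +
       (f0 - fm[i] - fm[j] + objective(par - ei - ej)) ) / (2 * h[i] * h[j])
  }
  cov_work <- 2 * solve(H)
  # jacobian of natural = exp(working), identity for power thetas
  jac <- ifelse(log_scale, abs(estimates), 1)
  se_nat <- sqrt(pmax(diag(cov_work), 0)) * jac
  100 * se_nat / abs(estimates)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("FOCE fit:", if (x$converged) "converged" else "NOT converged",
      sprintf("| OFV %.3f | %d observations\n", x$ofv, x$n_obs))
  tab <- data.frame(estimate = signif(x$estimates, 4))
  if (!is.null(x$rse)) tab$rse_pct <- signif(x$rse, 3)
  print(tab)
  invisible(x)
}

#' Empirical Bayes evaluation of a model at fixed parameters
#'
#' Computes the FOCE objective and per-subject conditional etas without any
#' parameter optimization; useful for diagnostics of a shipped model.
#'
#' @inheritParams fit_model
#' @return A `fit_result` (no standard errors).
#' @export
evaluate_model <- function(spec, dataset, settings = foce_settings()) {
  designs <- dataset_designs(dataset, spec$ka)
  eta_state <- new.env(parent = emptyenv())
  eta_state$eta <- numeric(length(designs))
  final <- ofv_from_designs(designs, spec, spec$sigma_add^2,
                            spec$omega_cl^2, eta_state, settings,
                            keep_parts = TRUE)
  eta_hat <- vapply(seq_along(designs), function(i)
    if (designs[[i]]$n > 0) final$parts[[i]]$eta else NA_real_, numeric(1))
  names(eta_hat) <- vapply(dataset$subjects, `[[`, "", "subject_id")
  estimates <- c(cl_std = spec$cl_allometry$standard_value,
                 v_std = spec$v_allometry$standard_value,
                 omega_cl = spec$omega_cl, sigma_add = spec$sigma_add)
  structure(list(spec = spec, estimates = estimates, rse = NULL,
                 ofv = final$ofv, eta_hat = eta_hat, converged = TRUE,
                 n_obs = final$n_obs, settings = settings),
            class = "fit_result")
}

#' Objective-function-value change threshold for covariate selection
#'
#' The chi-square quantile with 1 degree of freedom at significance `p`
#' (each candidate relation adds exactly one coefficient): 3.84 at p = 0.05
#' (forward inclusion) and 6.63 at p = 0.01 (backward retention).
#'
#' @param p Significance level.
#' @param df Degrees of freedom (default 1).
#' @return Threshold on the OFV change.
#' @export
delta_ofv_threshold <- function(p, df = 1) {
  stats::qchisq(1 - p, df = df)
}

#' Stepwise covariate selection by OFV change
#'
#' Forward pass: repeatedly adds the candidate giving the largest OFV
#' decrease while that decrease exceeds `qchisq(0.95, 1) = 3.84`; ties go to
#' the earliest candidate in declared order. Backward pass: removes any
#' included covariate whose removal increases the OFV by at most
#' `qchisq(0.99, 1) = 6.63`, repeating until the model is stable.
#'
#' @param base_spec [model_spec()] without the candidate relations.
#' @param candidates List of [covariate_relation()] templates, one
#'   coefficient each.
#' @param dataset [pk_dataset()].
#' @param settings [foce_settings()].
#' @param forward_p,backward_p Significance levels for the two passes.
#' @return List with `final_spec`, `final_fit`, and `selection_log`
#'   (data.frame of every tested step with its OFV change).
#' @export
stepwise_covariates <- function(base_spec, candidates, dataset,
                                settings = foce_settings(),
                                forward_p = 0.05, backward_p = 0.01) {
  fwd_thr <- delta_ofv_threshold(forward_p)
  bwd_thr <- delta_ofv_threshold(backward_p)
  log_rows <- list()
  note <- function(phase, cov, delta, action)
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      phase = phase, covariate = cov, delta_ofv = delta, action = action)

  refit <- function(spec) fit_model(spec, dataset, settings,
                                    compute_se = FALSE)
  current <- base_spec
  current_fit <- refit(current)
  remaining <- candidates
  # forward inclusion
  repeat {
    if (length(remaining) == 0) break
    deltas <- numeric(length(remaining)); fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      cand_spec <- current
      cand_spec$covariates <- c(current$covariates, list(remaining[[j]]))
      fits[[j]] <- refit(cand_spec)
      deltas[j] <- current_fit$ofv - fits[[j]]$ofv
    }
    best <- which.max(deltas)   # ties resolve to first in declared order
    for (j in seq_along(remaining))
      note("forward", remaining[[j]]$covariate_name, deltas[j],
           if (j == best && deltas[j] > fwd_thr) "included" else "not included")
    if (deltas[best] <= fwd_thr) break
    current$covariates <- c(current$covariates, list(remaining[[best]]))
    current <- fits[[best]]$spec
    current_fit <- fits[[best]]
    remaining <- remaining[-best]
  }
  # backward elimination
  repeat {
    if (length(current$covariates) == 0) break
    removed_any <- FALSE
    for (j in seq_along(current$covariates)) {
      reduced <- current
      reduced$covariates <- current$covariates[-j]
      red_fit <- refit(reduced)
      increase <- red_fit$ofv - current_fit$ofv
      keep <- increase > bwd_thr
      note("backward", current$covariates[[j]]$covariate_name, increase,
           if (keep) "retained" else "removed")
      if (!keep) {
        current <- red_fit$spec
        current_fit <- red_fit
        removed_any <- TRUE
        break
      }
    }
    if (!removed_any) break
  }
  list(final_spec = current_fit$spec, final_fit = current_fit,
       selection_log = do.call(rbind, log_rows))
}
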