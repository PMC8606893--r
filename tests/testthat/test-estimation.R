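test_that("the conditional eta matches a brute-force grid search", {
  spec <- published_model()
  # one-observation toy subject, grid over eta in [-3, 3] at 1e-4 steps
  s <- make_subject(weight = 15, dose = 0.4, obs_times = 36, conc = 12)
  grid <- seq(-3, 3, by = 1e-4)
  penalized <- vapply(grid, function(eta) {
    f <- predict_individual(spec, s, eta = eta, times = 36)
    sum((12 - f)^2) / spec$sigma_add^2 + eta^2 / spec$omega_cl^2
  }, numeric(1))
  eta_grid <- grid[which.min(penalized)]
  res <- conditional_eta(spec, s)
  expect_true(res$converged)
  expect_equal(res$eta_hat, eta_grid, tolerance = 1e-3)
  expect_gt(res$curvature, 0)
})

test_that("eta is zero for on-prediction data and unpenalized in the wide-prior limit", {
  spec <- published_model()
  s <- make_on_prediction_subject(spec, weight = 25, dose = 0.6)
  expect_equal(conditional_eta(spec, s)$eta_hat, 0, tolerance = 1e-6)

  # omega -> large: the mode approaches the unpenalized least-squares eta
  s2 <- make_subject(weight = 25, dose = 0.6, obs_times = c(12, 24, 48),
                     conc = c(6, 7, 8))
  wide <- spec; wide$omega_cl <- 1e4
  ls_eta <- optimize(function(eta) {
    f <- predict_individual(spec, s2, eta = eta)
    sum((s2$observations$conc - f)^2)
  }, c(-4, 4), tol = 1e-9)$minimum
  expect_equal(conditional_eta(wide, s2)$eta_hat, ls_eta, tolerance = 1e-4)
})

test_that("the FOCE objective agrees with adaptive-quadrature marginal likelihood on small instances", {
  set.seed(77)
  for (rep in 1:20) {
    spec <- model_spec(cl_std = runif(1, 6, 18), v_std = runif(1, 150, 500),
                       omega_cl = runif(1, 0.1, 0.45),
                       sigma_add = runif(1, 1, 4))
    n_sub <- sample(1:3, 1)
    subs <- lapply(seq_len(n_sub), function(i) {
      s <- make_subject(paste0("T", i), weight = runif(1, 5, 50),
                        dose = runif(1, 0.2, 1.5),
                        obs_times = sort(sample(c(12, 24, 36, 60, 84),
                                                sample(1:3, 1))))
      true <- predict_individual(spec, s, eta = rnorm(1, 0, spec$omega_cl),
                                 times = s$observations$time)
      s$observations$conc <- pmax(true +
                                    rnorm(length(true), 0, spec$sigma_add), 0.1)
      s
    })
    ds <- pk_dataset(subs)
    expect_lt(abs(foce_objective(spec, ds) - quadrature_ofv(spec, ds)), 0.5)
  }
})

test_that("the objective is permutation-invariant and collapses correctly at omega = 0", {
  spec <- published_model()
  ds <- generate_cohort(cohort_spec(n_subjects = 10, seed = 31))
  perm <- pk_dataset(rev(ds$subjects))
  expect_equal(foce_objective(spec, ds), foce_objective(spec, perm))

  fo <- spec; fo$omega_cl <- 0
  manual <- 0
  for (s in ds$subjects) {
    obs <- s$observations[!s$observations$bql, , drop = FALSE]
    f <- predict_individual(fo, s, eta = 0, times = obs$time)
    manual <- manual + sum((obs$conc - f)^2) / fo$sigma_add^2 +
      nrow(obs) * log(fo$sigma_add^2)
  }
  expect_equal(foce_objective(fo, ds), manual)

  # including the constant shifts the OFV by exactly n log(2 pi)
  n_obs <- sum(vapply(ds$subjects, function(s) sum(!s$observations$bql), 1L))
  with_const <- foce_objective(spec, ds,
                               foce_settings(ofv_constant = "include"))
  expect_equal(with_const - foce_objective(spec, ds), n_obs * log(2 * pi))
})

test_that("near-noiseless rich data recovers the generating parameters", {
  gm <- model_spec(cl_std = 11.3, v_std = 388, omega_cl = 0,
                   sigma_add = 0.01)
  ds <- generate_cohort(cohort_spec(n_subjects = 20,
                                    sampling_design = "rich", seed = 5,
                                    generating_model = gm))
  fit <- fit_model(model_spec(8, 250, omega_cl = 0.1, sigma_add = 0.5), ds,
                   compute_se = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["cl_std"]), 11.3, tolerance = 0.02)
  expect_equal(unname(fit$estimates["v_std"]), 388, tolerance = 0.02)
  # optimality: fitted OFV no worse than at the generating parameters
  expect_lte(fit$ofv, foce_objective(gm, ds) + 1e-6)
})

test_that("FOCE recovery is unbiased over replicate cohorts with little censoring", {
  gm <- published_model()
  reps <- generate_recovery_suite(gm, n_subjects = 200, design = "rich",
                                  n_replicates = 20, seed = 42,
                                  dose_rate_range = c(0.08, 0.08))
  est <- vapply(reps, function(ds)
    fit_model(model_spec(8, 250, omega_cl = 0.2, sigma_add = 2), ds,
              compute_se = FALSE)$estimates, numeric(4))
  cl_bias <- stats::median(est["cl_std", ] / 11.3 - 1)
  om_bias <- stats::median(est["omega_cl", ] / 0.303 - 1)
  expect_lt(abs(cl_bias), 0.05)
  expect_lt(abs(om_bias), 0.15)
})

test_that("standard errors are finite and informative for a well-posed fit", {
  gm <- published_model()
  ds <- generate_cohort(cohort_spec(n_subjects = 60,
                                    sampling_design = "rich", seed = 13,
                                    dose_rate_range = c(0.08, 0.08),
                                    generating_model = gm))
  fit <- fit_model(model_spec(9, 300, omega_cl = 0.25, sigma_add = 3), ds)
  expect_true(all(is.finite(fit$rse)))
  expect_true(all(fit$rse > 0 & fit$rse < 100))
})

test_that("covariate-selection thresholds come from the chi-square quantile function", {
  expect_equal(round(delta_ofv_threshold(0.05), 2), 3.84)
  expect_equal(round(delta_ofv_threshold(0.01), 2), 6.63)
})

test_that("stepwise selection includes a real covariate effect and rejects a null one", {
  alb <- covariate_relation("ALB", "power", theta = 1.2,
                            covariate_median = 38)
  gm <- model_spec(11.3, 388, omega_cl = 0.25, sigma_add = 2,
                   covariates = list(alb))
  ds <- generate_cohort(cohort_spec(n_subjects = 40, seed = 9,
                                    generating_model = gm))
  cands <- list(covariate_relation("ALB", "power", 0, 38),
                covariate_relation("AGE", "power", 0, 6.8))
  sel <- stepwise_covariates(model_spec(8, 300, omega_cl = 0.2,
                                        sigma_add = 2), cands, ds)
  kept <- vapply(sel$final_spec$covariates, `[[`, "", "covariate_name")
  expect_identical(kept, "ALB")
  log <- sel$selection_log
  expect_gt(log$delta_ofv[log$phase == "forward" &
                            log$covariate == "ALB"][1], 3.84)
  expect_true(all(log$delta_ofv[log$covariate == "AGE"] < 3.84))
  expect_identical(log$action[log$phase == "backward"], "retained")
  expect_equal(sel$final_fit$estimates[["theta_ALB"]], 1.2, tolerance = 0.3)
})

test_that("selection on null data stays near its nominal type-I level", {
  gm <- model_spec(11.3, 388, omega_cl = 0.25, sigma_add = 2)
  included <- logical(10)
  set.seed(55)
  seeds <- sample.int(1e6, 10)
  for (r in 1:10) {
    ds <- generate_cohort(cohort_spec(n_subjects = 30, seed = seeds[r],
                                      generating_model = gm))
    sel <- stepwise_covariates(
      model_spec(10, 350, omega_cl = 0.2, sigma_add = 2),
      list(covariate_relation("ALB", "power", 0, 38)), ds)
    included[r] <- length(sel$final_spec$covariates) > 0
  }
  # nominal rate 5% per test; well under the 20% screening bound
  expect_lt(mean(included), 0.20)
})
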