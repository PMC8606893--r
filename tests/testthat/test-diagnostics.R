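test_that("CWRES reduces to the plain weighted residual when omega is zero", {
  spec <- published_model()
  spec$omega_cl <- 0
  ds <- generate_cohort(cohort_spec(n_subjects = 8, seed = 41))
  ev <- evaluate_model(spec, ds)
  cw <- compute_cwres(ev, ds)
  manual <- unlist(lapply(ds$subjects, function(s) {
    obs <- s$observations[!s$observations$bql, , drop = FALSE]
    (obs$conc - predict_individual(spec, s, 0, obs$time)) / spec$sigma_add
  }))
  expect_equal(cw$cwres, unname(manual))
})

test_that("CWRES vanishes for data lying on the population predictions", {
  spec <- published_model()
  spec$sigma_add <- 1e-4
  subs <- lapply(1:4, function(i)
    make_on_prediction_subject(spec, paste0("P", i), weight = 10 * i,
                               dose = 0.2 * i))
  ds <- pk_dataset(subs)
  cw <- compute_cwres(evaluate_model(spec, ds), ds)
  expect_true(all(abs(cw$cwres) < 1e-4))
})

test_that("CWRES is approximately standard normal under self-simulation", {
  gm <- published_model()
  ds <- generate_cohort(cohort_spec(n_subjects = 125, seed = 17,
                                    dose_rate_range = c(0.08, 0.10),
                                    lloq = 0))
  cw <- compute_cwres(evaluate_model(gm, ds), ds)
  expect_gte(nrow(cw), 490)
  expect_lt(abs(mean(cw$cwres)), 0.1)
  expect_lt(abs(var(cw$cwres) - 1), 0.2)
})

test_that("the goodness-of-fit table is complete and consistent", {
  gm <- published_model()
  ds <- generate_cohort(cohort_spec(n_subjects = 15, seed = 43))
  ev <- evaluate_model(gm, ds)
  tab <- goodness_of_fit_table(ev, ds)
  n_obs <- sum(vapply(ds$subjects, function(s) sum(!s$observations$bql), 1L))
  expect_equal(nrow(tab), n_obs)
  # normal-quantile column is monotone in CWRES rank
  ord <- order(tab$cwres)
  expect_true(all(diff(tab$cwres_normal_quantile[ord]) > 0))
  # population and individual predictions coincide when variability is off
  no_iiv <- gm; no_iiv$omega_cl <- 0
  tab0 <- goodness_of_fit_table(evaluate_model(no_iiv, ds), ds)
  expect_equal(tab0$population_prediction, tab0$individual_prediction)
})

test_that("bootstrap intervals collapse for cloned near-noiseless subjects", {
  spec <- model_spec(11.3, 388, omega_cl = 0.15, sigma_add = 0.05)
  proto <- make_on_prediction_subject(spec, weight = 20, dose = 0.5,
                                      obs_times = c(2, 6, 12, 24, 48))
  set.seed(61)
  subs <- lapply(1:12, function(i) {
    s <- proto
    s$subject_id <- paste0("C", i)
    s$observations$conc <- s$observations$conc + rnorm(5, 0, 0.05)
    s
  })
  ds <- pk_dataset(subs)
  bt <- bootstrap_model(spec, ds, n_replicates = 12, seed = 3)
  width <- with(bt$summary, (ci_upper - ci_lower) / estimate)
  expect_true(all(width[bt$summary$parameter %in% c("cl_std", "v_std")] <
                    0.02))
  # the default replicate count follows standard practice for this analysis
  expect_equal(eval(formals(bootstrap_model)$n_replicates), 1000)
})

test_that("bootstrap medians track the full-data estimate", {
  gm <- published_model()
  ds <- generate_cohort(cohort_spec(n_subjects = 50, seed = 23))
  bt <- bootstrap_model(gm, ds, n_replicates = 30, seed = 5)
  expect_lte(bt$n_failed, 3)
  s <- bt$summary
  cl <- s[s$parameter == "cl_std", ]
  expect_lt(abs(cl$boot_median / cl$estimate - 1), 0.10)
  expect_true(all(s$ci_lower <= s$estimate & s$estimate <= s$ci_upper))
})

test_that("prediction correction is exact for homogeneous cohorts and scale-invariant", {
  gm <- published_model()
  # identical subjects: correction factor 1, pc-VPC equals the plain VPC
  set.seed(71)
  subs <- lapply(1:10, function(i) {
    s <- make_subject(paste0("H", i), weight = 20, dose = 0.5,
                      obs_times = c(12, 36, 72, 120))
    s$observations$conc <- predict_individual(gm, s, rnorm(1, 0, 0.3),
                                              times = s$observations$time)
    s
  })
  ds <- pk_dataset(subs)
  ev <- evaluate_model(gm, ds)
  v <- pc_vpc(ev, ds, n_simulations = 100, bins = 4, seed = 9)
  y <- unlist(lapply(subs, function(s) s$observations$conc))
  times <- unlist(lapply(subs, function(s) s$observations$time))
  for (b in seq_len(nrow(v$bins))) {
    in_bin <- times >= v$bins$t_lo[b] & times <= v$bins$t_hi[b]
    expect_equal(v$bins$obs_p50[b],
                 unname(quantile(y[in_bin], 0.5)))
  }

  # rescaling every dose (and hence every concentration) by a constant
  # rescales the pc-VPC tables by exactly that constant
  scale_ds <- function(ds, k) {
    ds$subjects <- lapply(ds$subjects, function(s) {
      s$doses$amount <- s$doses$amount * k
      s$observations$conc <- s$observations$conc * k
      s
    })
    ds
  }
  ds2 <- generate_cohort(cohort_spec(n_subjects = 12, seed = 83,
                                     dose_rate_range = c(0.06, 0.09)))
  k <- 3
  ds2s <- scale_ds(ds2, k)
  sigk <- gm; sigk$sigma_add <- gm$sigma_add * k  # keep the model consistent
  v1 <- pc_vpc(evaluate_model(gm, ds2), ds2, n_simulations = 100, seed = 7)
  v2 <- pc_vpc(evaluate_model(sigk, ds2s), ds2s, n_simulations = 100,
               seed = 7)
  expect_equal(v2$bins$obs_p50, k * v1$bins$obs_p50, tolerance = 1e-8)
  expect_equal(v2$bins$sim_p50_lo, k * v1$bins$sim_p50_lo, tolerance = 1e-8)
})

test_that("pc-VPC bands cover self-simulated data at the expected rate", {
  gm <- published_model()
  stats <- lapply(1:20, function(s) {
    d <- generate_cohort(cohort_spec(n_subjects = 15, seed = 300 + s,
                                     dose_rate_range = c(0.05, 0.08)))
    e <- evaluate_model(gm, d)
    v <- pc_vpc(e, d, n_simulations = 200, seed = 400 + s)
    b <- v$bins
    c(coverage = vpc_band_coverage(v),
      median_in_band = all(b$obs_p50 >= b$sim_p50_lo &
                             b$obs_p50 <= b$sim_p50_hi))
  })
  m <- do.call(rbind, stats)
  expect_gte(mean(m[, "coverage"]), 0.90)
  expect_gte(mean(m[, "median_in_band"]), 0.90)
})
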