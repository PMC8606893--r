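# Model-evaluation machinery: conditional weighted residuals under the
# FOCE linearization, goodness-of-fit tables, nonparametric bootstrap of
# the fit, and the prediction-corrected visual predictive check.

#' Conditional weighted residuals
#'
#' `CWRES_i = C_i^(-1/2) (y_i - E_i)` with `E_i = f_i(eta_hat) - G_i
#' eta_hat` and `C_i = G_i omega^2 G_i' + sigma^2 I`, the conditional
#' linearization used by the FOCE objective; one residual per non-BQL
#' observation. Under a correct model CWRES are approximately standard
#' normal.
#'
#' @param fit [fit_model()] or [evaluate_model()] result.
#' @param dataset The [pk_dataset()] the fit was obtained on.
#' @return `data.frame` with columns `subject`, `time`, `observed`,
#'   `population_prediction`, `individual_prediction`, `cwres`.
#' @export
compute_cwres <- function(fit, dataset) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  spec <- fit$spec
  sigma2 <- spec$sigma_add^2
  omega2 <- spec$omega_cl^2
  rows <- list()
  for (i in seq_along(dataset$subjects)) {
    s <- dataset$subjects[[i]]
    d <- subject_design(s, spec$ka)
    if (d$n == 0) next
    eta <- fit$eta_hat[[i]]
    cl0 <- typical_clearance(spec, d$weight, d$covariates)
    v <- typical_volume(spec, d$weight, d$covariates)
    ce <- conc_eta(d, eta, cl0, v, spec$ka)
    f0 <- conc_eta(d, 0, cl0, v, spec$ka)$f
    e_cond <- ce$f - ce$g * eta
    cmat <- omega2 * tcrossprod(ce$g) + diag(sigma2, d$n)
    eig <- eigen(cmat, symmetric = TRUE)
    if (any(eig$values <= 0))
      stop("non-positive-definite conditional covariance for subject ", d$id)
    c_inv_sqrt <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
    cwres <- as.numeric(c_inv_sqrt %*% (d$y - e_cond))
    rows[[length(rows) + 1]] <- data.frame(
      subject = d$id, time = d$times, observed = d$y,
      population_prediction = f0, individual_prediction = ce$f,
      cwres = cwres)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Goodness-of-fit table
#'
#' The paired columns behind the standard diagnostic panels: observations
#' against population and individual predictions, CWRES against time and
#' predictions, and the normal quantiles matching each CWRES rank (for the
#' quantile-quantile panel).
#'
#' @inheritParams compute_cwres
#' @return `data.frame`; one row per non-BQL observation.
#' @export
goodness_of_fit_table <- function(fit, dataset) {
  tab <- compute_cwres(fit, dataset)
  r <- rank(tab$cwres, ties.method = "first")
  tab$cwres_normal_quantile <- stats::qnorm((r - 0.5) / nrow(tab))
  tab
}

#' Nonparametric bootstrap of the population-model fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' each replicate (started from the full-data estimates), and reports
#' percentile confidence bounds. Non-converged or failed replicates are
#' dropped and counted.
#'
#' @param spec Starting [model_spec()].
#' @param dataset [pk_dataset()].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param settings [foce_settings()].
#' @return Object of class `bootstrap_result`: `summary` data.frame
#'   (parameter, estimate, boot_median, ci_lower, ci_upper),
#'   `n_replicates`, `n_failed`, and the replicate `estimates` matrix.
#' @export
bootstrap_model <- function(spec, dataset, n_replicates = 1000, seed = 1,
                            settings = foce_settings()) {
  stopifnot(n_replicates >= 1)
  full_fit <- fit_model(spec, dataset, settings, compute_se = FALSE)
  start_spec <- full_fit$spec
  n <- length(dataset$subjects)
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_replicates, replace = TRUE),
                  nrow = n_replicates)
  reps <- vector("list", n_replicates)
  n_failed <- 0
  for (b in seq_len(n_replicates)) {
    idx <- draws[b, ]
    subs <- lapply(seq_along(idx), function(k) {
      s <- dataset$subjects[[idx[k]]]
      s$subject_id <- sprintf("B%d_%d", b, k)
      s
    })
    boot_ds <- pk_dataset(subs)
    ft <- try(fit_model(start_spec, boot_ds, settings, compute_se = FALSE),
              silent = TRUE)
    if (inherits(ft, "try-error") || !ft$converged) {
      n_failed <- n_failed + 1
    } else {
      reps[[b]] <- ft$estimates
    }
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) == 0) stop("all bootstrap replicates failed")
  est_mat <- do.call(rbind, reps)
  qs <- apply(est_mat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(parameter = colnames(est_mat),
                        estimate = unname(full_fit$estimates),
                        boot_median = unname(qs[2, ]),
                        ci_lower = unname(qs[1, ]),
                        ci_upper = unname(qs[3, ]))
  structure(list(summary = summary, n_replicates = n_replicates,
                 n_failed = n_failed, estimates = est_mat,
                 full_fit = full_fit), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  print(x$summary, digits = 4)
  invisible(x)
}

# Quantile-based time bins with equal observation counts; bins holding
# fewer than two observations are merged with their neighbor.
make_time_bins <- function(times, n_bins) {
  edges <- unique(stats::quantile(times, probs = seq(0, 1, length.out =
                                                       n_bins + 1)))
  if (length(edges) < 2) edges <- c(min(times), max(times) + 1)
  edges[1] <- edges[1] - 1e-9
  bin <- cut(times, edges, include.lowest = TRUE, labels = FALSE)
  bin <- match(bin, sort(unique(bin)))     # drop empty bin numbers
  repeat {
    counts <- tabulate(bin, nbins = max(bin))
    small <- which(counts > 0 & counts < 2)
    if (length(small) == 0 || length(unique(bin)) == 1) break
    b <- small[1]
    neighbor <- if (b == max(bin)) b - 1 else b + 1
    bin[bin == b] <- neighbor
    bin <- match(bin, sort(unique(bin)))   # renumber 1..K
  }
  bin
}

#' Prediction-corrected visual predictive check
#'
#' Observed and simulated concentrations are normalized to each time bin's
#' median population prediction (each value multiplied by bin-median PRED /
#' own PRED), removing between-subject differences in dose and weight.
#' Observed prediction-corrected percentiles (2.5/50/97.5) per bin are
#' compared with 95% bands of the same percentiles across simulation
#' replicates of the fitted model at the original design.
#'
#' @param fit [fit_model()] or [evaluate_model()] result.
#' @param dataset [pk_dataset()].
#' @param n_simulations Number of simulated replicate datasets
#'   (default 1000).
#' @param bins Number of quantile-based time bins (default 6).
#' @param seed Integer seed for the simulations.
#' @return Object of class `vpc_result` with a `bins` data.frame: per bin
#'   the time span, observation count, observed prediction-corrected
#'   percentiles, and lower/upper simulated band bounds for each
#'   percentile.
#' @export
pc_vpc <- function(fit, dataset, n_simulations = 1000, bins = 6, seed = 1) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (n_simulations < 100) stop("need at least 100 simulation replicates")
  spec <- fit$spec
  designs <- dataset_designs(dataset, spec$ka)
  designs <- designs[vapply(designs, function(d) d$n > 0, logical(1))]
  pred <- unlist(lapply(designs, function(d) {
    cl0 <- typical_clearance(spec, d$weight, d$covariates)
    v <- typical_volume(spec, d$weight, d$covariates)
    conc_eta(d, 0, cl0, v, spec$ka)$f
  }))
  y <- unlist(lapply(designs, `[[`, "y"))
  times <- unlist(lapply(designs, `[[`, "times"))
  bin <- make_time_bins(times, bins)
  k <- max(bin)
  bin_med_pred <- vapply(seq_len(k), function(b)
    stats::median(pred[bin == b]), numeric(1))
  corr <- bin_med_pred[bin] / pred
  pc_obs <- y * corr
  probs <- c(0.025, 0.5, 0.975)
  obs_pct <- t(vapply(seq_len(k), function(b)
    stats::quantile(pc_obs[bin == b], probs), numeric(3)))

  n_sub <- length(designs)
  n_per <- vapply(designs, `[[`, integer(1), "n")
  set.seed(seed)
  sim_pct <- array(NA_real_, dim = c(n_simulations, k, 3))
  for (r in seq_len(n_simulations)) {
    sims <- unlist(lapply(seq_len(n_sub), function(i) {
      d <- designs[[i]]
      cl0 <- typical_clearance(spec, d$weight, d$covariates)
      v <- typical_volume(spec, d$weight, d$covariates)
      eta <- stats::rnorm(1, 0, spec$omega_cl)
      conc_eta(d, eta, cl0, v, spec$ka)$f +
        stats::rnorm(d$n, 0, spec$sigma_add)
    }))
    pc_sim <- sims * corr
    sim_pct[r, , ] <- t(vapply(seq_len(k), function(b)
      stats::quantile(pc_sim[bin == b], probs), numeric(3)))
  }
  band_lo <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.025)
  band_hi <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.975)
  band_q1 <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.25)
  band_q3 <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.75)
  out <- data.frame(
    bin = seq_len(k),
    t_lo = vapply(seq_len(k), function(b) min(times[bin == b]), numeric(1)),
    t_hi = vapply(seq_len(k), function(b) max(times[bin == b]), numeric(1)),
    n_obs = vapply(seq_len(k), function(b) sum(bin == b), numeric(1)),
    obs_p2.5 = obs_pct[, 1], obs_p50 = obs_pct[, 2],
    obs_p97.5 = obs_pct[, 3],
    sim_p2.5_lo = band_lo[, 1], sim_p2.5_hi = band_hi[, 1],
    sim_p50_lo = band_lo[, 2], sim_p50_hi = band_hi[, 2],
    sim_p50_q1 = band_q1[, 2], sim_p50_q3 = band_q3[, 2],
    sim_p97.5_lo = band_lo[, 3], sim_p97.5_hi = band_hi[, 3])
  structure(list(bins = out, n_simulations = n_simulations, seed = seed),
            class = "vpc_result")
}

#' Fraction of observed pc-VPC percentile points inside their simulated bands
#'
#' @param vpc A [pc_vpc()] result.
#' @return Proportion in `[0, 1]` over the 3 percentiles x bins grid.
#' @export
vpc_band_coverage <- function(vpc) {
  b <- vpc$bins
  inside <- c(b$obs_p2.5 >= b$sim_p2.5_lo & b$obs_p2.5 <= b$sim_p2.5_hi,
              b$obs_p50 >= b$sim_p50_lo & b$obs_p50 <= b$sim_p50_hi,
              b$obs_p97.5 >= b$sim_p97.5_lo & b$obs_p97.5 <= b$sim_p97.5_hi)
  mean(inside)
}
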