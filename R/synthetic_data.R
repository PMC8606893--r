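# Virtual therapeutic-drug-monitoring cohorts with the statistical
# structure the analysis assumes: allometric typical values, lognormal
# between-subject variability on clearance, additive assay noise, and
# censoring at the immunoassay's 3.5 ng/ml lower quantitation limit. The
# default cohort emulates the study population: 15 children weighing
# 4-54 kg on twice-daily oral sirolimus with sparse, trough-dominated
# sampling.

#' Specification of a synthetic TDM cohort
#'
#' @param n_subjects Number of subjects (default 15).
#' @param weight_range Body-weight range, kg (default 4-54).
#' @param weight_dist `"uniform"` over the range, or `"truncnorm"` with the
#'   study population's mean 22.27 and SD 9.87 kg truncated to the range.
#' @param dose_rate_range Daily dose range, mg/kg/day, split q12h.
#' @param sampling_design `"trough_sparse"` (3-6 pre-dose samples over
#'   weeks, imitating TDM practice) or `"rich"` (6 post-dose samples across
#'   one interval plus 3 troughs over 14 days; needed when the volume of
#'   distribution must be identifiable).
#' @param n_samples_per_subject Trough count for the sparse design (3-6).
#' @param seed Integer seed.
#' @param generating_model [model_spec()] used to simulate concentrations.
#' @param lloq Lower limit of quantitation, ng/ml; simulated observations
#'   below it are flagged BQL.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15, weight_range = c(4, 54),
                        weight_dist = c("uniform", "truncnorm"),
                        dose_rate_range = c(0.04, 0.08),
                        sampling_design = c("trough_sparse", "rich"),
                        n_samples_per_subject = 4, seed = 1,
                        generating_model = published_model(), lloq = 3.5) {
  weight_dist <- match.arg(weight_dist)
  sampling_design <- match.arg(sampling_design)
  stopifnot(n_subjects >= 1, weight_range[1] > 0,
            weight_range[1] < weight_range[2])
  if (sampling_design == "trough_sparse" &&
      (n_samples_per_subject < 3 || n_samples_per_subject > 6))
    stop("trough_sparse design supports 3-6 samples per subject")
  structure(list(n_subjects = n_subjects, weight_range = weight_range,
                 weight_dist = weight_dist,
                 dose_rate_range = dose_rate_range,
                 sampling_design = sampling_design,
                 n_samples_per_subject = n_samples_per_subject,
                 seed = seed, generating_model = generating_model,
                 lloq = lloq), class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Sampling times (hours) for one subject under a q12h regimen.
design_times <- function(design, n_samples) {
  if (design == "rich") {
    # absorption-phase samples after the morning dose on day 7 plus three
    # troughs over two weeks
    sort(c(144 + c(0.5, 1, 2, 4, 8, 11), c(120, 240, 336)))
  } else {
    troughs <- c(72, 168, 336, 504, 672, 840)   # days 3, 7, 14, 21, 28, 35
    troughs[seq_len(n_samples)]
  }
}

# Distractor covariates (no effect on concentrations by construction);
# mean, SD and truncation bounds follow the study cohort's demographics.
distractor_covariates <- function(n) {
  list(AGE = rtruncnorm1(n, 7.29, 3.11, 0.12, 16.39),
       ALB = rtruncnorm1(n, 37.82, 7.52, 21.6, 46.4),
       SCR = rtruncnorm1(n, 32.36, 16.18, 16, 76),
       HCT = rtruncnorm1(n, 33.19, 5.26, 23, 43.4))
}

#' Generate a synthetic TDM cohort
#'
#' Samples body weights, assigns twice-daily regimens at a per-kg daily
#' dose drawn uniformly from `dose_rate_range`, simulates true
#' concentrations under the generating model with a subject-level
#' `eta ~ N(0, omega^2)` on clearance, adds observation-level additive
#' noise `eps ~ N(0, sigma^2)`, and flags observations below the assay's
#' lower quantitation limit as BQL (negative simulated values are truncated
#' at 0 and flagged).
#'
#' @param spec [cohort_spec()].
#' @return A valid [pk_dataset()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  gm <- spec$generating_model
  n <- spec$n_subjects
  weights <- if (spec$weight_dist == "uniform")
    stats::runif(n, spec$weight_range[1], spec$weight_range[2])
  else
    rtruncnorm1(n, 22.27, 9.87, spec$weight_range[1], spec$weight_range[2])
  rates <- stats::runif(n, spec$dose_rate_range[1], spec$dose_rate_range[2])
  etas <- stats::rnorm(n, 0, gm$omega_cl)
  covs <- distractor_covariates(n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    times <- design_times(spec$sampling_design, spec$n_samples_per_subject)
    dose_amt <- rates[i] * weights[i] / 2
    doses <- dose_record(time = 0, amount = dose_amt, interval = 12)
    subj <- pk_subject(sprintf("S%03d", i), weights[i], doses,
                       observation_record(numeric(0), numeric(0)),
                       covariates = lapply(covs, `[[`, i))
    true_conc <- predict_individual(gm, subj, eta = etas[i], times = times)
    obs_conc <- true_conc + stats::rnorm(length(times), 0, gm$sigma_add)
    bql <- obs_conc < spec$lloq
    obs_conc[bql] <- spec$lloq   # flagged records carry the limit itself
    subj$observations <- observation_record(times, obs_conc, bql)
    subjects[[i]] <- subj
  }
  ds <- pk_dataset(subjects)
  attr(ds, "true_eta") <- etas
  attr(ds, "dose_rates") <- rates
  ds
}

#' Generate replicate cohorts for parameter-recovery experiments
#'
#' Replicates share the design but use independent sub-seeds derived
#' deterministically from the master seed.
#'
#' @param generating_model [model_spec()].
#' @param n_subjects Subjects per replicate.
#' @param design Sampling design, `"rich"` or `"trough_sparse"`.
#' @param n_replicates Number of cohorts.
#' @param seed Master seed.
#' @param ... Further arguments to [cohort_spec()].
#' @return List of [pk_dataset()]s.
#' @export
generate_recovery_suite <- function(generating_model, n_subjects = 200,
                                    design = "rich", n_replicates = 5,
                                    seed = 1, ...) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_replicates)
  lapply(sub_seeds, function(s)
    generate_cohort(cohort_spec(n_subjects = n_subjects,
                                sampling_design = design, seed = s,
                                generating_model = generating_model, ...)))
}
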