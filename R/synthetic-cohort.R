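#' Simulation configuration for a synthetic cognitive-aging cohort
#'
#' Defaults emulate the marginal structure of a longitudinal aging cohort of
#' community-dwelling adults aged 65+: a three-way pathway mixture (normal
#' aging / stable MCI / dementia), entry ages centered near 81, annual visits
#' with scheduling jitter truncated by a dropout hazard, and onset ages for
#' stable MCI (mean 85.7, SD 6.05) and dementia (mean 88.2, SD 6.70) rounded
#' to the realized visit grid.
#'
#' @param n_subjects Number of subjects.
#' @param pathway_probs Probabilities for (normal, stableMCI, dementia);
#'   must sum to 1.
#' @param age_at_entry_dist `c(mean, sd, min)` for entry age (years); minimum
#'   defaults to 65 (the cohort inclusion age).
#' @param visit_interval_yr Nominal spacing of annual visits.
#' @param visit_jitter_yr Uniform jitter applied to each visit time.
#' @param max_visits Maximum number of visits per subject.
#' @param dropout_hazard Per-visit probability that follow-up ends.
#' @param mci_onset_dist,dementia_onset_dist `c(mean, sd)` of the onset-age
#'   distributions (years), truncated to follow-up and rounded to visits.
#' @param isolated_mci_prob Probability that any given pre-onset (or
#'   normal-path) visit carries a transient, non-consecutive MCI diagnosis.
#' @param dementia_mci_prob Probability that a dementia-path subject has a
#'   recorded stable-MCI phase before dementia (when follow-up allows it).
#' @param covariate_spec Named list; each element is
#'   `list(type = "binary", p = ...)` or `list(type = "normal", mean, sd)`.
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   configuration including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 300,
                       pathway_probs = c(normal = 0.590, stableMCI = 0.134, dementia = 0.276),
                       age_at_entry_dist = c(mean = 81.2, sd = 7.12, min = 65),
                       visit_interval_yr = 1, visit_jitter_yr = 0.1,
                       max_visits = 10, dropout_hazard = 0.12,
                       mci_onset_dist = c(mean = 85.7, sd = 6.05),
                       dementia_onset_dist = c(mean = 88.2, sd = 6.70),
                       isolated_mci_prob = 0.08,
                       dementia_mci_prob = 0.5,
                       covariate_spec = list(
                         sex_female = list(type = "binary", p = 0.752),
                         education_yr = list(type = "normal", mean = 15.3, sd = 3.05)),
                       seed = 1L) {
  if (abs(sum(pathway_probs) - 1) > 1e-12) stop("pathway_probs must sum to 1")
  if (any(pathway_probs < 0)) stop("pathway_probs must be non-negative")
  if (length(pathway_probs) != 3) stop("pathway_probs must have 3 elements")
  if (age_at_entry_dist[["min"]] < 65) stop("entry ages must be >= 65")
  if (visit_interval_yr <= 0) stop("visit_interval_yr must be positive")
  if (max_visits < 1) stop("max_visits must be >= 1")
  for (d in list(mci_onset_dist, dementia_onset_dist)) {
    if (d[["mean"]] + 4 * d[["sd"]] < age_at_entry_dist[["min"]])
      stop("onset distribution implies onset before entry for essentially all subjects")
  }
  structure(list(n_subjects = n_subjects, pathway_probs = unname(pathway_probs),
                 age_at_entry_dist = age_at_entry_dist,
                 visit_interval_yr = visit_interval_yr,
                 visit_jitter_yr = visit_jitter_yr,
                 max_visits = max_visits, dropout_hazard = dropout_hazard,
                 mci_onset_dist = mci_onset_dist,
                 dementia_onset_dist = dementia_onset_dist,
                 isolated_mci_prob = isolated_mci_prob,
                 dementia_mci_prob = dementia_mci_prob,
                 covariate_spec = covariate_spec, seed = as.integer(seed)),
            class = "sim_config")
}

rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# choose non-adjacent indices from `slots`, each kept with probability p,
# also excluding anything adjacent to `forbid_next_to`
choose_isolated <- function(slots, p, forbid = integer(0)) {
  picked <- integer(0)
  for (i in slots) {
    if (stats::runif(1) < p &&
        !((i - 1) %in% picked) && !((i + 1) %in% picked) &&
        !(i %in% forbid) && !((i + 1) %in% forbid) && !((i - 1) %in% forbid)) {
      picked <- c(picked, i)
    }
  }
  picked
}

#' Generate a synthetic longitudinal cohort with known pathway truth
#'
#' Samples each subject's pathway, entry age, visit schedule, diagnosis
#' sequence, onset ages, covariates, and self-reported sleep items. The
#' realized diagnosis sequence is always consistent with the sampled pathway:
#' normal-path subjects never have two consecutive MCI visits and never
#' dementia; stable-MCI subjects have exactly one run of >= 2 consecutive MCI
#' visits and no dementia; dementia-path subjects are demented from their
#' onset visit onward without reverting. Transient single-year MCI diagnoses
#' (which revert and do not define stable MCI) are sprinkled into pre-onset
#' and normal-path records. Truth onset ages are read off the realized visit
#' grid with the same convention used by [assign_pathway()] (first visit of
#' the earliest consecutive-MCI pair; first dementia visit).
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort`: `visits` (subject, visit, age,
#'   diagnosis, covariates, self-report items), `truth` (subject, pathway,
#'   mci_onset_age, dementia_onset_age), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  paths <- c("normal", "stableMCI", "dementia")
  visits_list <- vector("list", config$n_subjects)
  truth_list <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    pathway <- sample(paths, 1, prob = config$pathway_probs)
    entry <- rtruncnorm1(config$age_at_entry_dist[["mean"]],
                         config$age_at_entry_dist[["sd"]],
                         lo = config$age_at_entry_dist[["min"]])
    n_vis <- min(config$max_visits, 1 + stats::rgeom(1, config$dropout_hazard))
    if (pathway == "stableMCI") n_vis <- max(n_vis, 2)
    if (pathway == "dementia") n_vis <- max(n_vis, 1)
    ages <- entry + (seq_len(n_vis) - 1) * config$visit_interval_yr +
      c(0, stats::runif(n_vis - 1, -config$visit_jitter_yr, config$visit_jitter_yr))
    ages <- sort(ages)
    dx <- rep("NCI", n_vis)
    mci_onset <- NA_real_; dem_onset <- NA_real_
    if (pathway == "stableMCI") {
      raw <- rtruncnorm1(config$mci_onset_dist[["mean"]], config$mci_onset_dist[["sd"]])
      k <- which.min(abs(ages[seq_len(n_vis - 1)] - raw))  # needs a next visit
      dx[k:n_vis] <- "MCI"
      mci_onset <- ages[k]
      iso <- choose_isolated(seq_len(max(k - 2, 0)), config$isolated_mci_prob,
                             forbid = k)
      dx[iso] <- "MCI"
    } else if (pathway == "dementia") {
      raw_d <- rtruncnorm1(config$dementia_onset_dist[["mean"]], config$dementia_onset_dist[["sd"]])
      kd <- which.min(abs(ages - raw_d))
      dx[kd:n_vis] <- "dementia"
      dem_onset <- ages[kd]
      km <- NA_integer_
      if (kd >= 3 && stats::runif(1) < config$dementia_mci_prob) {
        raw_m <- rtruncnorm1(config$mci_onset_dist[["mean"]], config$mci_onset_dist[["sd"]])
        km <- which.min(abs(ages[seq_len(kd - 2)] - raw_m))
        dx[km:(kd - 1)] <- "MCI"
        mci_onset <- ages[km]
      }
      iso_max <- if (is.na(km)) kd - 2 else km - 2
      if (!is.na(iso_max) && iso_max >= 1) {
        iso <- choose_isolated(seq_len(iso_max), config$isolated_mci_prob,
                               forbid = c(km, kd))
        dx[iso] <- "MCI"
      }
    } else {
      iso <- choose_isolated(seq_len(n_vis), config$isolated_mci_prob)
      dx[iso] <- "MCI"
    }
    covs <- lapply(config$covariate_spec, function(cv) {
      if (cv$type == "binary") stats::rbinom(1, 1, cv$p)
      else stats::rnorm(1, cv$mean, cv$sd)
    })
    sr_tst <- pmin(pmax(stats::rnorm(n_vis, 7, 1), 3), 12)
    sr_bed <- (stats::rnorm(n_vis, 22.5, 0.8)) %% 24
    sr_wake <- (sr_bed + sr_tst) %% 24
    visits_list[[s]] <- data.frame(
      subject = sprintf("S%04d", s), visit = seq_len(n_vis), age = ages,
      diagnosis = dx, as.data.frame(covs),
      sr_tst = sr_tst, sr_bed = sr_bed, sr_wake = sr_wake)
    truth_list[[s]] <- data.frame(
      subject = sprintf("S%04d", s), pathway = pathway,
      mci_onset_age = mci_onset, dementia_onset_age = dem_onset)
  }
  structure(list(visits = do.call(rbind, visits_list),
                 truth = do.call(rbind, truth_list),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d visits (%s)\n",
              nrow(x$truth), nrow(x$visits),
              paste(sprintf("%s %d", names(table(x$truth$pathway)),
                            as.integer(table(x$truth$pathway))), collapse = ", ")))
  invisible(x)
}

#' Truth parameters for the feature-level trajectory simulator
#'
#' @param beta Named numeric vector of fixed-effect coefficients; names must
#'   match the design columns produced by [build_design()].
#' @param re_cov 2x2 positive-semidefinite covariance of the subject random
#'   intercept and age slope.
#' @param sigma2 Residual variance (>= 0).
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(beta, re_cov = matrix(0, 2, 2), sigma2 = 1) {
  re_cov <- as.matrix(re_cov)
  stopifnot(all(dim(re_cov) == c(2, 2)))
  if (max(abs(re_cov - t(re_cov))) > 1e-10) stop("re_cov must be symmetric")
  ev <- eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("re_cov must be positive semidefinite")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  structure(list(beta = beta, re_cov = re_cov, sigma2 = sigma2),
            class = "trajectory_params")
}

#' Simulate feature-level longitudinal outcomes from known truth
#'
#' Draws one outcome per visit from the trajectory model itself: the
#' fixed-effect linear predictor built with the same design construction the
#' estimator uses ([build_design()]), plus a subject-specific random intercept
#' and age slope drawn from `truth$re_cov`, plus Gaussian residual noise.
#' Intended for estimator-recovery testing: the returned table carries the
#' generating parameters as an attribute.
#'
#' @param cohort A [generate_cohort()] result.
#' @param truth A [trajectory_params()].
#' @param seed Integer seed.
#' @param center_age Age at which the design centers age (years).
#' @param covariates Covariate columns included in the design (default: the
#'   cohort's simulated covariates).
#' @return The cohort's visit table with an `outcome` column and attribute
#'   `truth`.
#' @export
simulate_feature_outcomes <- function(cohort, truth, seed, center_age = 82,
                                      covariates = intersect(names(cohort$config$covariate_spec),
                                                             names(cohort$visits))) {
  stopifnot(inherits(cohort, "synthetic_cohort"), inherits(truth, "trajectory_params"))
  set.seed(seed)
  dat <- merge(cohort$visits, cohort$truth, by = "subject", sort = FALSE)
  dat <- dat[order(dat$subject, dat$age), ]
  dat$outcome <- 0
  des <- build_design(dat, outcome = "outcome", center_age = center_age,
                      covariates = covariates)
  if (!setequal(names(truth$beta), colnames(des$X))) {
    stop("truth coefficient names do not match design columns; missing: ",
         paste(setdiff(colnames(des$X), names(truth$beta)), collapse = ", "),
         "; extra: ", paste(setdiff(names(truth$beta), colnames(des$X)), collapse = ", "))
  }
  beta <- truth$beta[colnames(des$X)]
  subj <- unique(dat$subject)
  if (max(abs(truth$re_cov)) == 0) {
    b <- matrix(0, length(subj), 2)
  } else {
    ev <- eigen(truth$re_cov, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
    b <- matrix(stats::rnorm(2 * length(subj)), ncol = 2) %*% t(L)
  }
  rownames(b) <- subj
  eps <- if (truth$sigma2 > 0) stats::rnorm(nrow(dat), 0, sqrt(truth$sigma2)) else 0
  dat$outcome <- as.numeric(des$X %*% beta) +
    b[dat$subject, 1] + b[dat$subject, 2] * des$age_c + eps
  attr(dat, "truth") <- truth
  attr(dat, "center_age") <- center_age
  dat
}

#' Parameters for the epoch-level actigraphy simulator
#'
#' The mean activity curve is the extended cosine model of
#' [fit_extended_cosine()]; counts inside the nightly sleep window are
#' multiplied by a suppression factor, nonwear insertions are runs of exactly
#' zero counts, and (optionally) negative-binomial noise with configurable
#' dispersion emulates the overdispersion typical of wrist actigraphy counts.
#'
#' @param minimum,amplitude,acrophase,alpha,beta Extended-cosine mean-curve
#'   parameters (counts, counts, clock hours, `[-1, 1]`, `> 0`).
#' @param dispersion Negative-binomial size parameter; `0` disables noise so
#'   counts equal the mean curve exactly.
#' @param sleep_onset,sleep_duration Nightly sleep window (clock hour, hours).
#' @param suppression Multiplier in `[0, 1)` applied to counts in the sleep
#'   window; must be `< 1` so sleep is detectable.
#' @param nonwear List of `c(start_h, duration_h)` nonwear insertions in
#'   elapsed hours from the recording start.
#' @param days Number of recorded days (>= 1).
#' @param start_clock_h Clock hour at which the recording starts (default
#'   noon, so every day is a complete noon-to-noon window).
#' @return A list of class `actigraphy_sim_params`.
#' @export
actigraphy_sim_params <- function(minimum = 10, amplitude = 100, acrophase = 14,
                                  alpha = 0.2, beta = 8, dispersion = 5,
                                  sleep_onset = 23.5, sleep_duration = 8,
                                  suppression = 0.02, nonwear = list(),
                                  days = 7, start_clock_h = 12) {
  if (days < 1) stop("days must be >= 1")
  if (suppression < 0 || suppression >= 1) stop("suppression must be in [0, 1)")
  if (sleep_duration < 0) stop("negative sleep duration")
  if (abs(alpha) > 1) stop("alpha must be in [-1, 1]")
  if (beta <= 0) stop("beta must be > 0")
  for (nw in nonwear) if (nw[2] < 0) stop("negative nonwear duration")
  structure(list(minimum = minimum, amplitude = amplitude, acrophase = acrophase,
                 alpha = alpha, beta = beta, dispersion = dispersion,
                 sleep_onset = sleep_onset, sleep_duration = sleep_duration,
                 suppression = suppression, nonwear = nonwear, days = days,
                 start_clock_h = start_clock_h),
            class = "actigraphy_sim_params")
}

# closed-form mean curve of the simulator, exported for oracle checks
#' @rdname actigraphy_sim_params
#' @param clock_h Clock hours at which to evaluate the mean activity curve.
#' @param params An `actigraphy_sim_params`.
#' @export
actigraphy_mean_curve <- function(params, clock_h) {
  cosv <- cos(2 * pi * (clock_h - params$acrophase) / 24)
  params$minimum + params$amplitude / (1 + exp(-params$beta * (cosv - params$alpha)))
}

#' Simulate an epoch-level actigraphy recording
#'
#' @param params An [actigraphy_sim_params()].
#' @param seed Integer seed.
#' @param subject,session Identifiers for the output series.
#' @return An [epoch_series] of 15 s epochs spanning `params$days` days.
#' @export
simulate_epoch_actigraphy <- function(params, seed, subject = "S1", session = 1L) {
  stopifnot(inherits(params, "actigraphy_sim_params"))
  set.seed(seed)
  n <- params$days * 24 * 240  # 240 15-s epochs per hour
  t_h <- (seq_len(n) - 1) * 15 / 3600
  clock <- (params$start_clock_h + t_h) %% 24
  mu <- actigraphy_mean_curve(params, clock)
  in_sleep <- ((clock - params$sleep_onset) %% 24) < params$sleep_duration
  mu[in_sleep] <- mu[in_sleep] * params$suppression
  counts <- if (params$dispersion > 0) {
    stats::rnbinom(n, mu = mu, size = params$dispersion)
  } else mu
  for (nw in params$nonwear) {
    counts[t_h >= nw[1] & t_h < nw[1] + nw[2]] <- 0
  }
  start <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC") + params$start_clock_h * 3600
  epoch_series(counts, epoch_s = 15, start = start,
               subject = subject, session = session)
}
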