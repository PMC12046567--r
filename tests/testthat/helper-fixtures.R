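# Fixtures built in code; no stored data.

# A sharp rectangular day/night 60 s series starting at noon: `day_level`
# counts except `night_level` inside the nightly sleep window.
make_day60 <- function(days = 1, sleep_onset = 23.5, sleep_dur = 8,
                       day_level = 150, night_level = 0) {
  n <- days * 1440
  clock <- (12 + (seq_len(n) - 1) / 60) %% 24
  asleep <- ((clock - sleep_onset) %% 24) < sleep_dur
  epoch_series(ifelse(asleep, night_level, day_level), epoch_s = 60,
               start = as.POSIXct("2020-01-01 12:00:00", tz = "UTC"))
}

# A trajectory_fit with known coefficients, for closed-form contrast checks.
# `beta` names must come from the design vocabulary of build_design().
fake_fit <- function(beta, vcov = NULL, var_int = 0, sigma2 = 1, center_age = 82) {
  if (is.null(vcov)) vcov <- diag(1e-4, length(beta))
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov = vcov,
                 varcomp = list(var_intercept = var_int, var_slope = 0,
                                cov_int_slope = 0, sigma2 = sigma2),
                 p_values = stats::setNames(rep(0, length(beta)), names(beta)),
                 terms = NULL, logLik = NA_real_, n_obs = 0L,
                 boundary = FALSE, engine = "manual",
                 center_age = center_age, cov_means = numeric(0)),
            class = "trajectory_fit")
}

# Truth-coefficient template aligned with a cohort's design columns.
zero_beta <- function(cohort, covariates = character(0)) {
  dat <- merge(cohort$visits, cohort$truth, by = "subject")
  dat$outcome <- 0
  des <- build_design(dat, covariates = covariates)
  stats::setNames(rep(0, ncol(des$X)), colnames(des$X))
}

# clock hour of a POSIXct, in [0, 24)
clock_of <- function(t) as.numeric(t - trunc(t, "days"), units = "hours")

# signed circular difference a - b wrapped to (-12, 12]
circ_diff_h <- function(a, b) (a - b + 12) %% 24 - 12
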