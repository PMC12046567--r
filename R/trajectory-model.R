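#' Build the cubic-spline trajectory design
#'
#' Constructs the fixed-effect design for the trajectory model: polynomial
#' terms of centered age (`age`, `age2`, `age3`), pathway main effects
#' (normal is the reference), interactions of every age term with each
#' pathway, one truncated-cubic knot term per diagnosis event
#' (`knot_mci = ((age - k_MCI)+)^3`, `knot_dem = ((age - k_dem)+)^3`, each
#' evaluated at the subject's own onset age and zero for subjects without
#' that onset), and mean-centered covariates. A single truncated cubic per
#' knot keeps fitted trajectories continuous with continuous first and second
#' derivatives at each onset, so diagnosis-related change is gradual rather
#' than an elbow.
#'
#' @param data Data.frame with columns `subject`, `age`, `pathway`,
#'   `mci_onset_age`, `dementia_onset_age`, the outcome, and any covariates.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (numeric;
#'   each is centered at its mean, so the typical-participant prediction is
#'   the prediction at zero for all covariate columns).
#' @param weights Optional name of an observation-weight column (number of
#'   valid actigraphy days for actigraphy outcomes; all 1 for self-report).
#' @param center_age Centering age in years (default 82, a typical median
#'   first-visit age in aging cohorts).
#' @return A list of class `trajectory_design`: `y`, `X`, `subject`,
#'   `weights`, `age_c`, `terms` (per-column metadata), `center_age`,
#'   `cov_means`.
#' @export
build_design <- function(data, outcome = "outcome", covariates = character(0),
                         weights = NULL, center_age = 82) {
  need <- c("subject", "age", "pathway", "mci_onset_age", "dementia_onset_age", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(data$pathway %in% c("normal", "stableMCI", "dementia")))
    stop("pathway must be normal/stableMCI/dementia")
  bad <- data$pathway == "dementia" & is.na(data$dementia_onset_age)
  if (any(bad)) stop("dementia-pathway subject(s) without dementia onset age: ",
                     paste(unique(data$subject[bad]), collapse = ", "))
  a <- data$age - center_age
  p_mci <- as.numeric(data$pathway == "stableMCI")
  p_dem <- as.numeric(data$pathway == "dementia")
  k_mci <- ifelse(is.na(data$mci_onset_age), Inf, data$mci_onset_age)
  k_dem <- ifelse(is.na(data$dementia_onset_age), Inf, data$dementia_onset_age)
  X <- cbind(
    `(Intercept)` = 1, age = a, age2 = a^2, age3 = a^3,
    path_mci = p_mci, path_dem = p_dem,
    age_path_mci = a * p_mci, age2_path_mci = a^2 * p_mci, age3_path_mci = a^3 * p_mci,
    age_path_dem = a * p_dem, age2_path_dem = a^2 * p_dem, age3_path_dem = a^3 * p_dem,
    knot_mci = pmax(data$age - k_mci, 0)^3,
    knot_dem = pmax(data$age - k_dem, 0)^3)
  terms <- data.frame(
    term = colnames(X),
    type = c("intercept", rep("age_main", 3), rep("path_main", 2),
             rep("age_path", 6), rep("knot", 2)),
    order = c(0, 1:3, 0, 0, 1:3, 1:3, 3, 3),
    path = c(NA, NA, NA, NA, "mci", "dem",
             rep("mci", 3), rep("dem", 3), NA, NA))
  cov_means <- numeric(0)
  if (length(covariates)) {
    cv <- as.matrix(data[covariates])
    if (!is.numeric(cv)) stop("covariates must be numeric columns")
    cov_means <- colMeans(cv)
    cv <- sweep(cv, 2, cov_means)
    X <- cbind(X, cv)
    terms <- rbind(terms, data.frame(term = covariates, type = "covariate",
                                     order = 0, path = NA))
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(w <= 0 | is.na(w))) stop("weights must be positive")
  structure(list(y = data[[outcome]], X = X,
                 subject = factor(data$subject), weights = w, age_c = a,
                 terms = terms, center_age = center_age, cov_means = cov_means),
            class = "trajectory_design")
}

# drop named columns from a design
design_drop <- function(design, drop) {
  keep <- setdiff(colnames(design$X), drop)
  design$X <- design$X[, keep, drop = FALSE]
  design$terms <- design$terms[design$terms$term %in% keep, ]
  design
}

wls_fit <- function(design) {
  X <- design$X; y <- design$y
  w <- design$weights / mean(design$weights)
  fit <- stats::lm.wfit(X, y, w)
  p <- ncol(X); n <- nrow(X)
  rss <- sum(w * fit$residuals^2)
  sigma2 <- rss / max(n - p, 1)
  XtWX <- crossprod(X * sqrt(w))
  vc <- sigma2 * solve(XtWX)
  list(beta = fit$coefficients, vcov = vc, sigma2 = sigma2,
       var_int = 0, var_slope = 0, cov_is = 0, logLik = NA_real_,
       singular = TRUE, engine = "wls")
}

#' Fit the weighted linear mixed-effects spline model
#'
#' Fits `y = X beta + b0_i + b1_i * age_c + eps` by restricted maximum
#' likelihood, with an unstructured 2x2 covariance for the subject-specific
#' random intercept and age slope and residual variance `sigma^2 / w_i`
#' (observation `i` weighted by its number of valid actigraphy days). When
#' the mixed fit is degenerate (e.g., noise-free data where all variance
#' components vanish), the fixed effects are returned from the
#' weighted-least-squares solution with zero variance components and a
#' boundary flag.
#'
#' @param design A [build_design()] result (must be full column rank).
#' @return A list of class `trajectory_fit`: `beta`, `vcov`, `varcomp`
#'   (`var_intercept`, `var_slope`, `cov_int_slope`, `sigma2`), `p_values`
#'   (Wald t, residual df = n - rank), `terms`, `logLik`, `n_obs`,
#'   `boundary`, `engine`, plus the design metadata needed for prediction.
#' @export
fit_mixed_spline <- function(design) {
  stopifnot(inherits(design, "trajectory_design"))
  qrX <- qr(design$X * sqrt(design$weights))
  if (qrX$rank < ncol(design$X))
    stop("fixed-effect design is rank deficient; drop aliased columns first")
  nm <- colnames(design$X)
  # perfectly interpolated data (noise-free truth): the mixed model is
  # degenerate and the WLS solution is exact
  wls0 <- wls_fit(design)
  if (wls0$sigma2 <= 1e-12 * (stats::var(design$y) + 1e-300)) {
    res <- wls0
    return(finish_fit(res, design))
  }
  dd <- as.data.frame(design$X)
  names(dd) <- nm
  dd$.y <- design$y
  # only relative weights matter; normalizing to mean 1 (and rounding away
  # the last-ulp division noise) makes the fit exactly invariant to
  # rescaling all weights by a constant
  dd$.w <- signif(design$weights / mean(design$weights), 12)
  dd$.subject <- design$subject; dd$.age_c <- design$age_c
  fml <- stats::as.formula(paste0(
    ".y ~ 0 + ", paste0("`", nm, "`", collapse = " + "),
    " + (1 + .age_c | .subject)"))
  res <- tryCatch({
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = dd, weights = .w, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.nobs.vs.nlev = "ignore",
                   check.nobs.vs.nRE = "ignore"))))
    vcm <- lme4::VarCorr(fit)$.subject
    beta <- lme4::fixef(fit)
    names(beta) <- nm
    vc <- as.matrix(stats::vcov(fit))
    dimnames(vc) <- list(nm, nm)
    list(beta = beta, vcov = vc, sigma2 = stats::sigma(fit)^2,
         var_int = vcm[1, 1], var_slope = vcm[2, 2], cov_is = vcm[1, 2],
         logLik = as.numeric(stats::logLik(fit)),
         singular = lme4::isSingular(fit), engine = "lmer")
  }, error = function(e) wls_fit(design))
  if (any(!is.finite(res$beta)) || any(!is.finite(diag(res$vcov))))
    res <- wls_fit(design)
  finish_fit(res, design)
}

finish_fit <- function(res, design) {
  n <- nrow(design$X)
  se <- sqrt(pmax(diag(res$vcov), 0))
  tval <- res$beta / se
  df_resid <- max(n - length(res$beta), 1)
  pv <- 2 * stats::pt(-abs(tval), df_resid)
  structure(list(beta = res$beta, vcov = res$vcov,
                 varcomp = list(var_intercept = res$var_int,
                                var_slope = res$var_slope,
                                cov_int_slope = res$cov_is,
                                sigma2 = res$sigma2),
                 p_values = pv, terms = design$terms,
                 logLik = res$logLik, n_obs = n,
                 boundary = res$singular, engine = res$engine,
                 center_age = design$center_age, cov_means = design$cov_means),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %d terms, n = %d (%s%s)\n", length(x$beta),
              x$n_obs, x$engine, if (x$boundary) ", boundary" else ""))
  cat(sprintf("  variance components: intercept %.4g, age slope %.4g, cov %.4g, residual %.4g\n",
              x$varcomp$var_intercept, x$varcomp$var_slope,
              x$varcomp$cov_int_slope, x$varcomp$sigma2))
  invisible(x)
}

# terms currently removable under the hierarchy: an age x pathway interaction
# only at the highest retained order for its pathway; an age main effect only
# at the highest retained main order and with no interaction of equal or
# higher order remaining; knot terms always; mains/covariates never
eligible_terms <- function(terms) {
  el <- character(0)
  ap <- terms[terms$type == "age_path", ]
  for (p in unique(ap$path)) {
    sub <- ap[ap$path == p, ]
    el <- c(el, sub$term[sub$order == max(sub$order)])
  }
  am <- terms[terms$type == "age_main", ]
  if (nrow(am)) {
    k <- max(am$order)
    if (!nrow(ap) || max(ap$order) < k) el <- c(el, am$term[am$order == k])
  }
  c(el, terms$term[terms$type == "knot"])
}

#' Backward elimination of non-significant trajectory terms
#'
#' Starting from the full model, repeatedly removes the single eligible term
#' with the largest p-value at or above `alpha` and refits, until every
#' eligible term is significant or none remain. Only the highest-order age
#' terms, age-by-pathway interactions, and knot terms are ever eligible;
#' the hierarchy is preserved (no term is removed while a higher-order term
#' containing it remains, and an age main effect is retained while an
#' interaction of equal or higher order remains). Pathway main effects,
#' the intercept, and covariates are never removed.
#'
#' @param model A [fit_mixed_spline()] fit of the full design.
#' @param design The matching [build_design()] design.
#' @param alpha Significance level for retention (default 0.05).
#' @return The final `trajectory_fit`, with an `eliminated` element listing
#'   the removed terms in order.
#' @export
backward_eliminate <- function(model, design, alpha = 0.05) {
  removed <- character(0)
  repeat {
    el <- eligible_terms(model$terms)
    pv <- model$p_values[el]
    pv <- pv[!is.na(pv)]
    if (!length(pv) || max(pv) < alpha) break
    worst <- names(pv)[which.max(pv)]
    removed <- c(removed, worst)
    design <- design_drop(design, worst)
    model <- fit_mixed_spline(design)
  }
  model$eliminated <- removed
  model
}

# fixed-effect row vector for a typical participant at (pathway, age) under a
# benchmark schedule; covariates at the reference profile (centered => 0)
typical_row <- function(model, pathway, age, k_mci = NA, k_dem = NA) {
  if (!pathway %in% c("normal", "stableMCI", "dementia"))
    stop("unknown pathway: ", pathway)
  if (!is.na(k_dem) && pathway != "dementia")
    stop("dementia knot supplied for a non-dementia pathway")
  if (!is.na(k_mci) && pathway == "normal")
    stop("MCI knot supplied for the normal pathway")
  a <- age - model$center_age
  p_mci <- as.numeric(pathway == "stableMCI")
  p_dem <- as.numeric(pathway == "dementia")
  vals <- c(`(Intercept)` = 1, age = a, age2 = a^2, age3 = a^3,
            path_mci = p_mci, path_dem = p_dem,
            age_path_mci = a * p_mci, age2_path_mci = a^2 * p_mci,
            age3_path_mci = a^3 * p_mci,
            age_path_dem = a * p_dem, age2_path_dem = a^2 * p_dem,
            age3_path_dem = a^3 * p_dem,
            knot_mci = if (is.na(k_mci)) 0 else pmax(age - k_mci, 0)^3,
            knot_dem = if (is.na(k_dem)) 0 else pmax(age - k_dem, 0)^3)
  x <- stats::setNames(rep(0, length(model$beta)), names(model$beta))
  common <- intersect(names(x), names(vals))
  x[common] <- vals[common]
  x
}

#' Predict the outcome for a typical participant
#'
#' Evaluates the fixed-effect trajectory at the covariate reference profile
#' (average covariate levels) for a given pathway and age, with the knot
#' terms evaluated at a benchmark diagnosis schedule.
#'
#' @param model A `trajectory_fit`.
#' @param pathway One of `"normal"`, `"stableMCI"`, `"dementia"`.
#' @param age Age in years.
#' @param k_mci,k_dem Assumed onset ages for the schedule (NA = no such
#'   onset; a dementia knot is only valid on the dementia pathway).
#' @return A list: `fit` (expected outcome), `se` (standard error from the
#'   coefficient covariance).
#' @export
predict_typical <- function(model, pathway, age, k_mci = NA, k_dem = NA) {
  x <- typical_row(model, pathway, age, k_mci, k_dem)
  list(fit = sum(x * model$beta),
       se = sqrt(drop(t(x) %*% model$vcov %*% x)))
}
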