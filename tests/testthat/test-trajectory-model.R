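toy_rows <- function() {
  data.frame(
    subject = c("A", "A", "B", "B", "B"),
    age = c(80, 85, 85, 90, 94),
    pathway = c("normal", "normal", "dementia", "dementia", "dementia"),
    mci_onset_age = c(NA, NA, 86, 86, 86),
    dementia_onset_age = c(NA, NA, 90, 90, 90),
    outcome = 1:5, w = c(1, 1, 2, 2, 2))
}

test_that("knot columns activate only past the subject's own onset", {
  des <- build_design(toy_rows(), weights = "w")
  X <- des$X
  expect_true(all(X[1:2, c("knot_mci", "knot_dem")] == 0))  # normal path
  expect_equal(unname(X[3, "knot_mci"]), 0)        # age 85 < onset 86
  expect_equal(unname(X[5, "knot_mci"]), (94 - 86)^3)
  expect_equal(unname(X[4, "knot_dem"]), 0)        # at the knot itself
  expect_equal(unname(X[5, "knot_dem"]), (94 - 90)^3)
  expect_equal(X[, "age"], des$age_c)
  expect_equal(unname(X[5, "age3_path_dem"]), (94 - 82)^3)
})

test_that("design validation catches schema errors", {
  d <- toy_rows()
  d$dementia_onset_age[3:5] <- NA
  expect_error(build_design(d), "without dementia onset age")
  d2 <- toy_rows(); d2$pathway[1] <- "unknown"
  expect_error(build_design(d2), "pathway must be")
  d3 <- toy_rows(); d3$w[1] <- 0
  expect_error(build_design(d3, weights = "w"), "weights must be positive")
})

test_that("noise-free data reproduce the generating coefficients exactly", {
  coh <- generate_cohort(sim_config(n_subjects = 80, seed = 3))
  beta <- zero_beta(coh)
  beta[] <- seq_along(beta) * 0.01
  tp <- trajectory_params(beta, re_cov = diag(0, 2), sigma2 = 0)
  out <- simulate_feature_outcomes(coh, tp, seed = 1, covariates = character(0))
  fit <- fit_mixed_spline(build_design(out))
  expect_lt(max(abs(fit$beta - beta[names(fit$beta)])), 1e-8)
})

test_that("with no random effects the fit matches the closed-form WLS oracle", {
  coh <- generate_cohort(sim_config(n_subjects = 250, seed = 14))
  beta <- zero_beta(coh)
  beta["(Intercept)"] <- 6; beta["age"] <- -0.05; beta["path_dem"] <- -0.3
  out <- simulate_feature_outcomes(coh, trajectory_params(beta, diag(0, 2), sigma2 = 1),
                                   seed = 5, covariates = character(0))
  des <- build_design(out)
  fit <- fit_mixed_spline(des)
  # independent closed-form WLS solution
  XtX <- crossprod(des$X)
  bw <- solve(XtX, crossprod(des$X, des$y))[, 1]
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta - bw) <= 3 * se))
})

test_that("estimates are invariant to rescaling all observation weights", {
  coh <- generate_cohort(sim_config(n_subjects = 100, seed = 8))
  beta <- zero_beta(coh); beta["(Intercept)"] <- 5; beta["age"] <- 0.1
  out <- simulate_feature_outcomes(coh, trajectory_params(beta, diag(c(.3, .01)), 0.5),
                                   seed = 2, covariates = character(0))
  out$w1 <- sample(5:10, nrow(out), replace = TRUE)
  out$w7 <- 7 * out$w1
  f1 <- fit_mixed_spline(build_design(out, weights = "w1"))
  f7 <- fit_mixed_spline(build_design(out, weights = "w7"))
  expect_equal(f1$beta, f7$beta, tolerance = 1e-6)
  expect_equal(f1$vcov, f7$vcov, tolerance = 1e-5)
})

test_that("rank-deficient designs are refused", {
  d <- toy_rows()
  d$dup <- d$age - 82
  des <- build_design(d, weights = "w")
  des$X <- cbind(des$X, dup = des$X[, "age"])
  des$terms <- rbind(des$terms, data.frame(term = "dup", type = "covariate",
                                           order = 0, path = NA))
  expect_error(fit_mixed_spline(des), "rank deficient")
})

test_that("predicted trajectories are C2-smooth across diagnosis knots", {
  # single-knot models: any value or slope jump at that knot shows up
  # directly since everything else is constant there
  knots <- list(knot_mci = list(term = "knot_mci", k = 86),
                knot_dem = list(term = "knot_dem", k = 90))
  for (kk in knots) {
    beta_k <- stats::setNames(c(4, 0.07), c("(Intercept)", kk$term))
    fit_k <- fake_fit(beta_k)
    fk <- function(a) predict_typical(fit_k, "dementia", a, k_mci = 86, k_dem = 90)$fit
    k <- kk$k
    expect_lt(abs(fk(k + 1e-6) - fk(k - 1e-6)), 1e-9)
    h <- 1e-3
    expect_lt(abs((fk(k + h) - fk(k)) / h - (fk(k) - fk(k - h)) / h), 1e-4)
  }
  # full model: a cubic fitted left of the knot extrapolates across it, so
  # nothing below the third derivative jumps
  beta <- c(`(Intercept)` = 4, age = 0.2, age2 = -0.01, knot_mci = 0.05,
            knot_dem = -0.08)
  fit <- fake_fit(beta)
  f <- function(a) predict_typical(fit, "dementia", a, k_mci = 86, k_dem = 90)$fit
  h <- 0.05
  for (k in c(86, 90)) {
    left <- k - h * (4:1)
    cub <- stats::lm(y ~ poly(a, 3, raw = TRUE),
                     data = data.frame(a = left, y = sapply(left, f)))
    right <- k + h * (1:3)
    pred <- stats::predict(cub, newdata = data.frame(a = right))
    expect_lt(max(abs(pred - sapply(right, f))), 1e-3)
  }
})

test_that("typical predictions evaluate the fixed-effect polynomial", {
  fit <- fake_fit(c(`(Intercept)` = 2, age = 0.5, age2 = 0.1, path_dem = -1,
                    knot_dem = 0.02))
  a <- 94 - 82
  expect_equal(predict_typical(fit, "normal", 94)$fit, 2 + 0.5 * a + 0.1 * a^2)
  expect_equal(predict_typical(fit, "dementia", 94, k_mci = 86, k_dem = 90)$fit,
               2 + 0.5 * a + 0.1 * a^2 - 1 + 0.02 * (94 - 90)^3)
  expect_error(predict_typical(fit, "normal", 94, k_dem = 90), "non-dementia")
  expect_error(predict_typical(fit, "normal", 94, k_mci = 86), "normal pathway")
})

test_that("intercept-only models predict the intercept with its own SE", {
  coh <- generate_cohort(sim_config(n_subjects = 50, seed = 4))
  beta <- zero_beta(coh); beta["(Intercept)"] <- 3
  out <- simulate_feature_outcomes(coh, trajectory_params(beta, diag(0, 2), 0.2),
                                   seed = 3, covariates = character(0))
  des <- build_design(out)
  keep <- "(Intercept)"
  des$X <- des$X[, keep, drop = FALSE]
  des$terms <- des$terms[des$terms$term %in% keep, ]
  fit <- fit_mixed_spline(des)
  for (pw in c("normal", "stableMCI")) {
    p <- predict_typical(fit, pw, 88, k_mci = if (pw == "normal") NA else 86)
    expect_equal(p$fit, unname(fit$beta["(Intercept)"]))
    expect_equal(p$se, sqrt(fit$vcov[1, 1]))
  }
})

test_that("backward elimination keeps fully significant models unchanged", {
  coh <- generate_cohort(sim_config(n_subjects = 400, seed = 19))
  beta <- zero_beta(coh)
  beta[] <- c(7, -0.3, 0.05, -0.01, 1, -1.5, 0.3, -0.05, 0.01,
              0.4, -0.06, 0.012, -0.05, -0.08)
  out <- simulate_feature_outcomes(coh, trajectory_params(beta, diag(c(.2, .005)), 0.3),
                                   seed = 6, covariates = character(0))
  des <- build_design(out)
  fit <- fit_mixed_spline(des)
  el <- backward_eliminate(fit, des)
  expect_length(el$eliminated, 0)
  expect_equal(el$beta, fit$beta)
})

test_that("elimination respects the term hierarchy", {
  coh <- generate_cohort(sim_config(n_subjects = 400, seed = 23))
  beta <- zero_beta(coh)
  beta[c("(Intercept)", "age", "path_dem")] <- c(7, -0.1, -0.5)
  out <- simulate_feature_outcomes(coh, trajectory_params(beta, diag(c(.3, .01)), 0.5),
                                   seed = 11, covariates = character(0))
  des <- build_design(out)
  fit <- backward_eliminate(fit_mixed_spline(des), des)
  rem <- fit$eliminated
  # cubic main effect can only fall after both cubic interactions
  i_age3 <- match("age3", rem)
  if (!is.na(i_age3)) {
    for (tm in c("age3_path_mci", "age3_path_dem")) {
      expect_true(match(tm, rem) < i_age3)
    }
  }
  # quadratic main only after cubic main and all order >= 2 interactions
  i_age2 <- match("age2", rem)
  if (!is.na(i_age2)) {
    expect_true(match("age3", rem) < i_age2)
    for (tm in c("age2_path_mci", "age2_path_dem"))
      expect_true(match(tm, rem) < i_age2)
  }
  # within each pathway, interactions fall from the top order down
  for (p in c("mci", "dem")) {
    o3 <- match(paste0("age3_path_", p), rem)
    o2 <- match(paste0("age2_path_", p), rem)
    if (!is.na(o2)) expect_true(!is.na(o3) && o3 < o2)
  }
})
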