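#' Fit the extended (sigmoidally transformed) cosine model
#'
#' Models the 24 h rest-activity rhythm as
#' `y(t) = min + amp * F(cos(2*pi*(t - phi)/24))` with the anti-logistic
#' transform `F(c) = 1 / (1 + exp(-beta * (c - alpha)))`. `min` is the
#' trough level, `amp` the peak-to-trough range, `phi` the acrophase (clock
#' hour of peak activity), `alpha` in `[-1, 1]` controls the relative width of
#' the active period (higher alpha = narrower peaks, more time at rest), and
#' `beta > 0` the steepness of the rest/active transition.
#'
#' Fitting is bounded nonlinear least squares (Levenberg-Marquardt) on
#' `bin_min`-minute means of the unmasked epochs, multi-started over acrophase
#' initial values. Convergence status is `"full"` when the best fit converged
#' with no active bound, `"partial"` when it converged with alpha or beta at a
#' bound, and `"failed"` otherwise (including degenerate near-constant input,
#' for which alpha and acrophase are unidentifiable and returned as `NA`).
#'
#' @param series An [epoch_series] (nonwear-masked; unmasked epochs are used).
#' @param bin_min Width of the time bins (minutes) averaged before fitting.
#' @param phi_starts Acrophase starting values (clock hours) for multi-start.
#' @param beta_max Upper bound for the steepness parameter.
#' @return A list of class `ext_cosine_fit`: `minimum`, `amplitude`,
#'   `acrophase`, `alpha`, `beta`, `status`, `rss`.
#' @export
fit_extended_cosine <- function(series, bin_min = 10,
                                phi_starts = c(0, 6, 12, 18), beta_max = 50) {
  ok <- !series$excluded
  t_h <- es_clock_hours(series)[ok]
  y <- series$counts[ok]
  failed <- list(minimum = NA_real_, amplitude = NA_real_, acrophase = NA_real_,
                 alpha = NA_real_, beta = NA_real_, status = "failed", rss = NA_real_)
  class(failed) <- "ext_cosine_fit"
  if (length(y) < 24 || stats::sd(y) < 1e-10) return(failed)
  bin <- floor((es_hours(series)[ok] * 60) / bin_min)
  yb <- tapply(y, bin, mean)
  tb <- tapply(t_h, bin, function(h) {
    # circular mean of clock hours within the bin
    a <- h * pi / 12
    (atan2(mean(sin(a)), mean(cos(a))) * 12 / pi) %% 24
  })
  df <- data.frame(t = as.numeric(tb), y = as.numeric(yb))
  best <- NULL
  for (phi0 in phi_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ m + A / (1 + exp(-beta * (cos(2 * pi * (t - phi) / 24) - alpha))),
        data = df,
        start = list(m = max(min(df$y), 0), A = max(diff(range(df$y)), 1e-3),
                     phi = phi0, alpha = 0, beta = 2),
        lower = c(0, 0, phi0 - 12, -1, 1e-3),
        upper = c(Inf, Inf, phi0 + 12, 1, beta_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed)
  p <- stats::coef(best$fit)
  if (p[["A"]] < 1e-3 * stats::sd(df$y) || p[["A"]] < 1e-8) return(failed)
  at_bound <- (abs(p[["alpha"]]) > 1 - 1e-6) ||
    (p[["beta"]] > beta_max - 1e-6) || (p[["beta"]] < 1e-3 + 1e-9)
  structure(list(minimum = unname(p[["m"]]), amplitude = unname(p[["A"]]),
                 acrophase = unname(p[["phi"]]) %% 24,
                 alpha = unname(p[["alpha"]]), beta = unname(p[["beta"]]),
                 status = if (at_bound) "partial" else "full", rss = best$rss),
            class = "ext_cosine_fit")
}

#' @export
print.ext_cosine_fit <- function(x, ...) {
  cat(sprintf("<ext_cosine_fit> status %s: min %.2f amp %.2f acrophase %.2fh alpha %.3f beta %.2f\n",
              x$status, x$minimum, x$amplitude, x$acrophase, x$alpha, x$beta))
  invisible(x)
}

#' Hourly mean counts from an epoch series
#'
#' Averages unmasked counts within each elapsed hour, dropping any trailing
#' partial day so the result length is a multiple of 24 (the convention of the
#' nonparametric rhythm statistics). Hours with no unmasked epochs are linearly
#' interpolated from neighboring hours.
#'
#' @param series An [epoch_series].
#' @return Numeric vector of hourly means, length a multiple of 24.
#' @export
hourly_means <- function(series) {
  hr <- floor(es_hours(series))
  x <- series$counts
  x[series$excluded] <- NA
  n_hr <- (max(hr) + 1) %/% 24 * 24
  if (n_hr == 0) return(numeric(0))
  out <- rep(NA_real_, n_hr)
  m <- tapply(x, hr, mean, na.rm = TRUE)
  pos <- as.integer(names(m)) + 1
  keep <- pos <= n_hr
  out[pos[keep]] <- as.numeric(m)[keep]
  out[is.nan(out)] <- NA
  if (anyNA(out)) {
    if (all(is.na(out))) return(out)
    out <- stats::approx(which(!is.na(out)), out[!is.na(out)],
                         xout = seq_along(out), rule = 2)$y
  }
  out
}

#' Interdaily stability (IS)
#'
#' The ratio of the variance of the 24 hour-of-day mean profile to the total
#' variance: `IS = N * sum_h (xbar_h - xbar)^2 / (24 * sum_i (x_i - xbar)^2)`
#' over `N` hourly values with hour-of-day means `xbar_h`. IS is 1 for a
#' pattern that repeats exactly every 24 h and 0 when the hour-of-day means
#' are flat; it indexes day-to-day consistency of the rest-activity rhythm.
#'
#' @param hourly Numeric vector of hourly mean counts; length must be >= 48 and
#'   a multiple of 24.
#' @return IS in `[0, 1]`, or `NA` (with a warning) for constant input.
#' @export
interdaily_stability <- function(hourly) {
  N <- length(hourly)
  if (N < 48 || N %% 24 != 0) stop("need >= 48 hourly values in whole days (multiple of 24)")
  tot <- sum((hourly - mean(hourly))^2)
  if (tot < 1e-12) {
    warning("IS undefined for constant series")
    return(NA_real_)
  }
  hmeans <- tapply(hourly, (seq_len(N) - 1) %% 24, mean)
  N * sum((hmeans - mean(hourly))^2) / (24 * tot)
}

#' Intradaily variability (IV)
#'
#' The normalized mean square of successive differences:
#' `IV = N * sum_{i>=2} (x_i - x_{i-1})^2 / ((N - 1) * sum_i (x_i - xbar)^2)`.
#' IV indexes within-day fragmentation of the rhythm; its nominal range is
#' `[0, 2]` (white noise gives values near 2), but the statistic itself is
#' unbounded above, so out-of-nominal values are returned with an
#' `out_of_range` attribute set.
#'
#' @param hourly Numeric vector of hourly mean counts, length >= 48.
#' @return IV (>= 0) with attribute `out_of_range`; `NA` with a warning for
#'   constant input.
#' @export
intradaily_variability <- function(hourly) {
  N <- length(hourly)
  if (N < 48) stop("need >= 48 hourly values")
  tot <- sum((hourly - mean(hourly))^2)
  if (tot < 1e-12) {
    warning("IV undefined for constant series")
    return(NA_real_)
  }
  iv <- N * sum(diff(hourly)^2) / ((N - 1) * tot)
  attr(iv, "out_of_range") <- iv > 2
  iv
}

# circular mean of clock hours, in [0, 24)
circular_mean_h <- function(h) {
  a <- h * pi / 12
  (atan2(mean(sin(a)), mean(cos(a))) * 12 / pi) %% 24
}

#' Summarize detected rest intervals for a session
#'
#' Computes the session's mean rest-interval length, the circular mean of the
#' nightly midpoints, and the log-transformed standard deviation of the
#' midpoints. Midpoints are unwrapped to `(-12, 12]` h deviations around their
#' circular mean before the SD is taken, and the SD is transformed as
#' `ln(SD + eps)` with a small floor `eps` so zero-variability sessions remain
#' finite.
#'
#' @param intervals Data.frame from [detect_sleep_intervals()].
#' @param min_intervals Minimum intervals (sleep-sample rule, default 5) below
#'   which all summaries are `NA`.
#' @param eps Floor added to the SD (hours) before the log; default 1/120 h
#'   (30 s).
#' @return A list: `mean_length_h`, `midpoint_h`, `midpoint_sd_h`,
#'   `log_midpoint_sd`, `n_intervals`.
#' @export
rest_interval_summaries <- function(intervals, min_intervals = 5, eps = 1 / 120) {
  n <- nrow(intervals)
  if (n < min_intervals) {
    return(list(mean_length_h = NA_real_, midpoint_h = NA_real_,
                midpoint_sd_h = NA_real_, log_midpoint_sd = NA_real_,
                n_intervals = n))
  }
  mu <- circular_mean_h(intervals$midpoint_h)
  dev <- (intervals$midpoint_h - mu + 12) %% 24 - 12  # deviations in (-12, 12]
  sd_h <- stats::sd(dev)
  list(mean_length_h = mean(intervals$duration_h),
       midpoint_h = mu,
       midpoint_sd_h = sd_h,
       log_midpoint_sd = log(sd_h + eps),
       n_intervals = n)
}

#' Midpoint of self-reported bed and wake times
#'
#' The midpoint of the bed-to-wake arc going forward in time, reported as a
#' clock hour in `[0, 24)`.
#'
#' @param bed,wake Clock hours in `[0, 24)`.
#' @return Midpoint clock hour, or `NA` when `bed == wake` (undefined).
#' @export
self_report_midpoint <- function(bed, wake) {
  out <- rep(NA_real_, length(bed))
  arc <- (wake - bed) %% 24
  ok <- !is.na(arc) & arc > 0
  out[ok] <- (bed[ok] + arc[ok] / 2) %% 24
  out
}

#' Extract all session features from a raw 15 s epoch series
#'
#' Runs the full per-session pipeline: nonwear flagging, FIR downsampling to
#' 60 s, rest-interval detection, valid-day accounting, extended-cosine fit,
#' and the nonparametric rhythm statistics. Features whose eligibility rule
#' fails (fewer than `min_days` valid recording or sleep days, failed cosinor
#' convergence) are `NA`.
#'
#' @param series A raw [epoch_series] with 15 s epochs.
#' @param min_days Valid-day requirement for sample eligibility.
#' @return One-row data.frame with columns `subject`, `session`, `alpha`,
#'   `IS`, `IV`, `IV_out_of_range`, `acrophase`, `rest_length_h`,
#'   `rest_midpoint_h`, `log_midpoint_sd`, `valid_recording_days`,
#'   `valid_sleep_days`, `rar_eligible`, `sleep_eligible`.
#' @export
extract_session_features <- function(series, min_days = 5) {
  s <- flag_nonwear(series)
  s60 <- downsample_to_60s(s)
  intervals <- detect_sleep_intervals(s60)
  vd <- count_valid_days(s60, intervals, min_days = min_days)
  out <- data.frame(subject = series$subject, session = series$session,
                    alpha = NA_real_, IS = NA_real_, IV = NA_real_,
                    IV_out_of_range = NA, acrophase = NA_real_,
                    rest_length_h = NA_real_, rest_midpoint_h = NA_real_,
                    log_midpoint_sd = NA_real_,
                    valid_recording_days = vd$valid_recording_days,
                    valid_sleep_days = vd$valid_sleep_days,
                    rar_eligible = vd$rar_eligible,
                    sleep_eligible = vd$sleep_eligible)
  if (vd$rar_eligible) {
    cf <- fit_extended_cosine(s60)
    if (cf$status != "failed") {
      out$alpha <- cf$alpha
      out$acrophase <- cf$acrophase
    }
    hm <- hourly_means(s60)
    if (length(hm) >= 48 && !anyNA(hm)) {
      is_v <- suppressWarnings(interdaily_stability(hm))
      iv_v <- suppressWarnings(intradaily_variability(hm))
      out$IS <- is_v
      out$IV <- as.numeric(iv_v)
      out$IV_out_of_range <- isTRUE(attr(iv_v, "out_of_range"))
    }
  }
  if (vd$sleep_eligible) {
    rs <- rest_interval_summaries(intervals, min_intervals = min_days)
    out$rest_length_h <- rs$mean_length_h
    out$rest_midpoint_h <- rs$midpoint_h
    out$log_midpoint_sd <- rs$log_midpoint_sd
  }
  out
}
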