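#' Benchmark age sets and diagnosis schedules
#'
#' A benchmark set is four strictly increasing evaluation ages plus the
#' assumed diagnosis schedule for each pathway: normal stays undiagnosed
#' throughout; stable MCI has MCI onset at the second age; dementia has MCI
#' onset at the second age and dementia onset at the third. The primary set
#' is `{82, 86, 90, 94}`; `benchmark_sets()` also returns the four
#' sensitivity sets (shifted two years earlier `{80, 84, 88, 92}`, two years
#' later `{84, 88, 92, 96}`, three-year spacing `{82, 85, 88, 91}`, and a
#' longer initial normal period `{80, 86, 90, 94}`).
#'
#' @param ages Four strictly increasing ages (years).
#' @return `benchmark_set()`: a list of class `benchmark_set` with `ages` and
#'   `schedule(pathway)`. `benchmark_sets()`: a named list of all five sets.
#' @export
benchmark_set <- function(ages = c(82, 86, 90, 94)) {
  if (length(ages) != 4 || any(diff(ages) <= 0))
    stop("a benchmark set is four strictly increasing ages")
  structure(list(
    ages = ages,
    schedule = function(pathway) {
      switch(pathway,
             normal = list(k_mci = NA_real_, k_dem = NA_real_),
             stableMCI = list(k_mci = ages[2], k_dem = NA_real_),
             dementia = list(k_mci = ages[2], k_dem = ages[3]),
             stop("unknown pathway: ", pathway))
    }), class = "benchmark_set")
}

#' @rdname benchmark_set
#' @export
benchmark_sets <- function() {
  list(primary = benchmark_set(c(82, 86, 90, 94)),
       shift_earlier = benchmark_set(c(80, 84, 88, 92)),
       shift_later = benchmark_set(c(84, 88, 92, 96)),
       three_year = benchmark_set(c(82, 85, 88, 91)),
       long_normal = benchmark_set(c(80, 86, 90, 94)))
}

#' Model-based standardizer for contrasts
#'
#' The default denominator of the standardized contrast d: the SD of a single
#' observation for an average-age subject,
#' `sqrt(intercept variance + residual variance)`. Alternatives: `"residual"`
#' (residual SD only).
#'
#' @param model A `trajectory_fit`.
#' @param type `"population"` (default) or `"residual"`.
#' @return A positive scalar.
#' @export
contrast_sd <- function(model, type = c("population", "residual")) {
  type <- match.arg(type)
  s <- switch(type,
              population = sqrt(model$varcomp$var_intercept + model$varcomp$sigma2),
              residual = sqrt(model$varcomp$sigma2))
  if (!is.finite(s) || s <= 0) stop("standardizer is not positive; supply sigma_std explicitly")
  s
}

contrast_result <- function(kind, est, se, sigma_std, level = 0.95, meta) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  d <- est / sigma_std
  p <- if (se > 0) 2 * stats::pnorm(-abs(est / se)) else as.numeric(est == 0)
  cbind(data.frame(kind = kind), meta,
        data.frame(d = d, ci_lo = (est - z * se) / sigma_std,
                   ci_hi = (est + z * se) / sigma_std,
                   p = p, p_adj = NA_real_,
                   label = label_effect_size(d)))
}

#' Standardized within-pathway change between two ages
#'
#' Computes `d = (pred(to_age) - pred(from_age)) / sigma_std` for a typical
#' participant on one pathway under a benchmark set's diagnosis schedule,
#' with a Wald 95% CI from the contrast's standard error (the standardizer
#' treated as fixed).
#'
#' @param model A `trajectory_fit`.
#' @param pathway Pathway name.
#' @param set A [benchmark_set()].
#' @param from_age,to_age Ages (default: the set's first and last ages).
#' @param sigma_std Standardizer; default [contrast_sd()] of the model.
#' @param domain Sleep-health domain tag (`"amount"`, `"regularity"`,
#'   `"timing"`) carried into BH grouping.
#' @return One-row data.frame (a `ContrastResult`).
#' @export
within_pathway_change <- function(model, pathway, set = benchmark_set(),
                                  from_age = set$ages[1], to_age = set$ages[4],
                                  sigma_std = contrast_sd(model),
                                  domain = NA_character_) {
  sch <- set$schedule(pathway)
  x1 <- typical_row(model, pathway, from_age, sch$k_mci, sch$k_dem)
  x2 <- typical_row(model, pathway, to_age, sch$k_mci, sch$k_dem)
  cvec <- x2 - x1
  est <- sum(cvec * model$beta)
  se <- sqrt(drop(t(cvec) %*% model$vcov %*% cvec))
  contrast_result("within-change", est, se, sigma_std,
                  meta = data.frame(pathway = pathway, pathway_b = NA,
                                    from_age = from_age, to_age = to_age,
                                    age = NA_real_, domain = domain))
}

#' Standardized between-pathway difference at one age
#'
#' `d = (pred_A - pred_B) / sigma_std` at a single age, each pathway
#' evaluated under its own schedule from the benchmark set. Antisymmetric in
#' its pathway arguments.
#'
#' @inheritParams within_pathway_change
#' @param path_a,path_b Distinct pathway names.
#' @param age Evaluation age (conventionally the set's first or last age).
#' @return One-row data.frame (a `ContrastResult`).
#' @export
between_pathway_difference <- function(model, path_a, path_b, age,
                                       set = benchmark_set(),
                                       sigma_std = contrast_sd(model),
                                       domain = NA_character_) {
  if (identical(path_a, path_b)) stop("pathways must differ")
  sa <- set$schedule(path_a); sb <- set$schedule(path_b)
  xa <- typical_row(model, path_a, age, sa$k_mci, sa$k_dem)
  xb <- typical_row(model, path_b, age, sb$k_mci, sb$k_dem)
  cvec <- xa - xb
  est <- sum(cvec * model$beta)
  se <- sqrt(drop(t(cvec) %*% model$vcov %*% cvec))
  contrast_result("between-difference", est, se, sigma_std,
                  meta = data.frame(pathway = path_a, pathway_b = path_b,
                                    from_age = NA_real_, to_age = NA_real_,
                                    age = age, domain = domain))
}

#' Benjamini-Hochberg adjustment within (aim, domain) families
#'
#' Applies the BH step-up procedure separately within each group defined by
#' the grouping columns (by default `aim` and `domain`), writing the adjusted
#' p-values into `p_adj`.
#'
#' @param results Data.frame of contrast results with a raw `p` column.
#' @param by Grouping column names present in `results`.
#' @return `results` with `p_adj` filled in.
#' @export
adjust_bh <- function(results, by = c("aim", "domain")) {
  by <- intersect(by, names(results))
  g <- if (length(by)) interaction(results[by], drop = TRUE) else factor(rep(1, nrow(results)))
  for (lev in levels(g)) {
    i <- which(g == lev)
    results$p_adj[i] <- stats::p.adjust(results$p[i], method = "BH")
  }
  results
}

#' Effect-size label for a standardized contrast
#'
#' Conventional magnitude taxonomy on `|d|`: < 0.2 very small, 0.2-0.49
#' small, 0.5-0.79 moderate, >= 0.8 large.
#'
#' @param d Numeric vector of standardized contrasts.
#' @return Character vector of labels.
#' @export
label_effect_size <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "very small",
         ifelse(a < 0.5, "small",
                ifelse(a < 0.8, "moderate", "large")))
}

#' Run the full benchmark contrast grid
#'
#' For every fitted feature model and every benchmark set, computes the
#' within-pathway overall change (first to last age) for each pathway, the
#' within-pathway segment changes (between successive benchmark ages, with a
#' small offset after each interior boundary so segments do not overlap), and
#' the between-pathway differences for all three pathway pairs at the first
#' and last ages. Raw p-values are BH-adjusted within each (aim, domain)
#' family, where the aims are `within` (overall changes), `within_segment`,
#' `between_first`, and `between_last`.
#'
#' @param models Named list of `trajectory_fit` objects, one per feature.
#' @param sets Named list of [benchmark_set()]s (default all five).
#' @param domains Named character vector mapping feature names to domains;
#'   unnamed features get domain `NA` (their own BH family).
#' @param segment_offset Years added after each interior boundary for
#'   segment starts (default 0.1, matching schedules such as "MCI from
#'   86.1").
#' @return Long-format data.frame of labeled, BH-adjusted contrasts.
#' @export
run_benchmark_grid <- function(models, sets = benchmark_sets(),
                               domains = NULL, segment_offset = 0.1) {
  stopifnot(is.list(models), length(names(models)) == length(models))
  paths <- c("normal", "stableMCI", "dementia")
  pairs <- utils::combn(paths, 2, simplify = FALSE)
  rows <- list()
  for (f in names(models)) {
    m <- models[[f]]
    dom <- if (!is.null(domains) && f %in% names(domains)) domains[[f]] else NA_character_
    sstd <- contrast_sd(m)
    for (sname in names(sets)) {
      set <- sets[[sname]]
      a <- set$ages
      for (p in paths) {
        r <- within_pathway_change(m, p, set, sigma_std = sstd, domain = dom)
        r$aim <- "within"
        rows[[length(rows) + 1]] <- cbind(feature = f, set = sname, r)
        starts <- c(a[1], a[2] + segment_offset, a[3] + segment_offset)
        ends <- c(a[2], a[3], a[4])
        for (s in 1:3) {
          r <- within_pathway_change(m, p, set, from_age = starts[s],
                                     to_age = ends[s], sigma_std = sstd,
                                     domain = dom)
          r$aim <- "within_segment"
          rows[[length(rows) + 1]] <- cbind(feature = f, set = sname, r)
        }
      }
      for (pr in pairs) {
        for (age_i in c(1, 4)) {
          r <- between_pathway_difference(m, pr[1], pr[2], a[age_i], set,
                                          sigma_std = sstd, domain = dom)
          r$aim <- if (age_i == 1) "between_first" else "between_last"
          rows[[length(rows) + 1]] <- cbind(feature = f, set = sname, r)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # each benchmark set is its own analysis; families are (set, aim, domain)
  adjust_bh(out, by = c("set", "aim", "domain"))
}
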