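#' Flag nonwear periods
#'
#' Device removal shows up as long runs of exactly zero counts. Every maximal
#' run of zeros strictly longer than `threshold_h` hours is treated as nonwear,
#' and the full 24 h window centered on the run's midpoint (clipped to the
#' recording) is excluded from analysis. Counts are never altered, only the
#' exclusion mask.
#'
#' @param series An [epoch_series] (15 s or 60 s epochs).
#' @param threshold_h Zero-run length (hours) beyond which a run is nonwear.
#' @param window_h Length of the excluded window centered on the run midpoint.
#' @param center One of `"midpoint"` (default), `"start"`: where to center the
#'   excluded window on the qualifying run.
#' @return The series with its `excluded` mask updated (a union with any prior
#'   exclusions).
#' @export
flag_nonwear <- function(series, threshold_h = 4, window_h = 24,
                         center = c("midpoint", "start")) {
  center <- match.arg(center)
  n <- length(series$counts)
  if (n == 0) return(series)
  d <- series$epoch_s
  r <- rle(series$counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mask <- series$excluded
  for (k in which(r$values & r$lengths * d > threshold_h * 3600)) {
    # run covers time [(i0-1)d, i1*d); center the window per `center`
    t0 <- (starts[k] - 1) * d
    t1 <- ends[k] * d
    ctr <- if (center == "midpoint") (t0 + t1) / 2 else t0
    lo <- ctr - window_h * 3600 / 2
    hi <- ctr + window_h * 3600 / 2
    i <- seq_len(n)
    mask <- mask | ((i - 1) * d < hi & i * d > lo)
  }
  series$excluded <- mask
  series
}

#' Downsample a 15 s series to 60 s epochs
#'
#' Applies an anti-aliasing low-pass FIR filter (Hamming-windowed, 65 taps,
#' cutoff at the new Nyquist frequency of 1/120 Hz) as a zero-phase centered
#' convolution with reflection padding, then decimates 4:1 by averaging each
#' filtered block of four source epochs. A 60 s epoch is excluded if any of its
#' four source epochs is excluded.
#'
#' @param series An [epoch_series] with 15 s epochs.
#' @param taps Number of FIR taps (odd; default 65).
#' @return An [epoch_series] with 60 s epochs and length `floor(n/4)`.
#' @export
downsample_to_60s <- function(series, taps = 65) {
  if (series$epoch_s != 15) stop("downsample_to_60s expects 15 s epochs")
  n <- length(series$counts)
  if (n < taps) stop("series shorter than the FIR filter order (", taps, " epochs)")
  if (taps %% 2 != 1) stop("taps must be odd for a zero-phase centered filter")
  # normalized cutoff: (1/120 Hz) / (15 s Nyquist of 1/30 Hz) = 0.25
  h <- signal::fir1(taps - 1, 0.25, type = "low", window = signal::hamming(taps))
  h <- h / sum(h)  # exact unit DC gain so constant signals pass unchanged
  half <- (taps - 1) / 2
  x <- series$counts
  xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[n - seq_len(half)]))
  f <- stats::filter(xp, h, method = "convolution", sides = 2)
  f <- as.numeric(f)[(half + 1):(half + n)]
  f <- pmax(f, 0)
  n_out <- n %/% 4
  blk <- matrix(f[seq_len(n_out * 4)], nrow = 4)
  counts60 <- colMeans(blk)
  mask4 <- matrix(series$excluded[seq_len(n_out * 4)], nrow = 4)
  epoch_series(counts60, epoch_s = 60, start = series$start,
               subject = series$subject, session = series$session,
               excluded = apply(mask4, 2, any))
}

# Complete noon-to-noon windows within a recording. Returns a data.frame of
# window start times plus the epoch index range of each.
noon_windows <- function(series) {
  n <- length(series$counts)
  d <- series$epoch_s
  start_clock <- as.numeric(series$start - trunc(series$start, "days"), units = "hours")
  # hours from series start to the first noon boundary at or after the start
  to_noon <- (12 - start_clock) %% 24
  total_h <- n * d / 3600
  starts_h <- seq(to_noon, total_h - 24, by = 24)
  if (to_noon > total_h - 24) starts_h <- numeric(0)
  if (length(starts_h) == 0) {
    return(data.frame(window = integer(0), start_h = numeric(0),
                      i0 = integer(0), i1 = integer(0)))
  }
  i0 <- round(starts_h * 3600 / d) + 1
  i1 <- i0 + round(24 * 3600 / d) - 1
  keep <- i1 <= n
  data.frame(window = seq_along(starts_h)[keep], start_h = starts_h[keep],
             i0 = i0[keep], i1 = i1[keep])
}

# binary morphology on logical vectors; erosion defined by duality
morph_dilate <- function(x, half) {
  if (half == 0) return(x)
  n <- length(x)
  s <- stats::filter(c(rep(FALSE, half), x, rep(FALSE, half)),
                     rep(1, 2 * half + 1), sides = 2)
  as.numeric(s)[(half + 1):(half + n)] > 0
}
morph_erode <- function(x, half) !morph_dilate(!x, half)

#' Detect the principal nightly rest interval per day
#'
#' For each complete noon-to-noon window with sufficient unmasked data, rest is
#' classified by an adaptive threshold: counts are log-transformed
#' (`ln(count + 1)`), a 2-means split of the window's unmasked log-counts gives
#' two cluster centers, and the threshold is their midpoint. The binary rest
#' classification is smoothed by morphological closing then opening with a
#' `smooth_min`-minute structuring element, and the longest rest bout in the
#' window is taken as that day's rest interval. Candidate intervals longer than
#' `max_duration_h` (default 18 h) are discarded as invalid.
#'
#' @param series A nonwear-masked [epoch_series] with 60 s epochs.
#' @param min_unmasked_frac Minimum fraction of unmasked epochs for a window to
#'   be searched at all.
#' @param smooth_min Structuring-element length in minutes for the
#'   morphological smoothing.
#' @param max_duration_h Maximum plausible rest-interval duration in hours.
#' @return A data.frame with one row per detected interval: `window`, `onset`,
#'   `offset` (POSIXct), `duration_h`, `midpoint_h` (clock time in `[0, 24)`).
#' @export
detect_sleep_intervals <- function(series, min_unmasked_frac = 0.5,
                                   smooth_min = 30, max_duration_h = 18) {
  if (series$epoch_s != 60) stop("detect_sleep_intervals expects 60 s epochs")
  wins <- noon_windows(series)
  half <- floor(smooth_min / 2)
  out <- list()
  for (w in seq_len(nrow(wins))) {
    idx <- wins$i0[w]:wins$i1[w]
    ok <- !series$excluded[idx]
    if (mean(ok) < min_unmasked_frac) next
    lx <- log(series$counts[idx] + 1)
    rng <- range(lx[ok])
    if (diff(rng) < 1e-8) {
      # constant window: all-zero means rest throughout (killed by the cap);
      # constant activity means no detectable rest
      if (max(series$counts[idx][ok]) > 0) next
      rest <- ok
    } else {
      ctr0 <- stats::quantile(lx[ok], c(0.1, 0.9), names = FALSE)
      if (diff(ctr0) < 1e-8) ctr0 <- rng
      km <- stats::kmeans(lx[ok], centers = matrix(ctr0, ncol = 1))
      thr <- mean(km$centers)
      rest <- rep(FALSE, length(idx))
      rest[ok] <- lx[ok] < thr
      rest <- morph_dilate(morph_erode(morph_erode(morph_dilate(rest, half), half), half), half)
    }
    r <- rle(rest)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    best <- which(r$values)[which.max(r$lengths[r$values])]
    dur_h <- r$lengths[best] * series$epoch_s / 3600
    if (dur_h > max_duration_h || dur_h <= 0) next
    onset <- series$start + (idx[1] - 1 + starts[best] - 1) * series$epoch_s
    offset <- onset + dur_h * 3600
    onset_clock <- as.numeric(onset - trunc(onset, "days"), units = "hours")
    out[[length(out) + 1]] <- data.frame(
      window = wins$window[w], onset = onset, offset = offset,
      duration_h = dur_h, midpoint_h = (onset_clock + dur_h / 2) %% 24)
  }
  if (length(out) == 0) {
    return(data.frame(window = integer(0),
                      onset = as.POSIXct(character(0), tz = "UTC"),
                      offset = as.POSIXct(character(0), tz = "UTC"),
                      duration_h = numeric(0), midpoint_h = numeric(0)))
  }
  do.call(rbind, out)
}

#' Count valid recording and sleep days for a session
#'
#' A valid recording day is a complete noon-to-noon window with at least
#' `min_frac` of its epochs unmasked; a valid sleep day is a valid recording
#' day with a detected rest interval. Sessions enter the rest-activity rhythm
#' analytic sample with >= 5 valid recording days and the actigraphy sleep
#' sample with >= 5 valid sleep days.
#'
#' @param series A processed [epoch_series] (60 s, nonwear-masked).
#' @param intervals Output of [detect_sleep_intervals()] for the same series.
#' @param min_frac Minimum unmasked epoch fraction for a valid day.
#' @param min_days Valid-day requirement for sample eligibility.
#' @return A list: `valid_recording_days`, `valid_sleep_days`, `rar_eligible`,
#'   `sleep_eligible`.
#' @export
count_valid_days <- function(series, intervals, min_frac = 0.9, min_days = 5) {
  wins <- noon_windows(series)
  valid_rec <- logical(nrow(wins))
  for (w in seq_len(nrow(wins))) {
    idx <- wins$i0[w]:wins$i1[w]
    valid_rec[w] <- mean(!series$excluded[idx]) >= min_frac
  }
  has_sleep <- wins$window %in% intervals$window
  list(valid_recording_days = sum(valid_rec),
       valid_sleep_days = sum(valid_rec & has_sleep),
       rar_eligible = sum(valid_rec) >= min_days,
       sleep_eligible = sum(valid_rec & has_sleep) >= min_days)
}
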