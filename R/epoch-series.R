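#' Epoch-level activity series
#'
#' Container for one recording session of wrist-accelerometer activity counts:
#' a regular sequence of integrated activity counts (typically 15 s or 60 s
#' epochs) together with an exclusion mask used to drop nonwear and otherwise
#' invalid stretches from analysis.
#'
#' @param counts Numeric vector of non-negative activity counts, one per epoch.
#' @param epoch_s Epoch length in seconds (15 or 60).
#' @param start POSIXct start time of the first epoch (UTC assumed).
#' @param subject,session Identifiers carried through processing.
#' @param excluded Logical vector, same length as `counts`; `TRUE` marks epochs
#'   excluded from analysis. Defaults to all `FALSE`.
#'
#' @return An object of class `epoch_series`: a list with elements `counts`,
#'   `epoch_s`, `start`, `subject`, `session`, `excluded`.
#' @export
epoch_series <- function(counts, epoch_s, start = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                         subject = "S1", session = 1L, excluded = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("activity counts must be non-negative")
  if (!epoch_s %in% c(15, 60)) stop("epoch_s must be 15 or 60 seconds")
  if (is.null(excluded)) excluded <- rep(FALSE, length(counts))
  if (length(excluded) != length(counts)) stop("excluded mask must match counts length")
  structure(
    list(counts = counts, epoch_s = as.numeric(epoch_s),
         start = as.POSIXct(start, tz = "UTC"),
         subject = subject, session = session,
         excluded = as.logical(excluded)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  hrs <- length(x$counts) * x$epoch_s / 3600
  cat(sprintf("<epoch_series> subject %s session %s: %d epochs of %gs (%.1f h), %.1f%% excluded\n",
              x$subject, x$session, length(x$counts), x$epoch_s, hrs,
              100 * mean(x$excluded)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch timestamps and clock hours
#'
#' `es_times()` returns the POSIXct timestamp of each epoch start;
#' `es_hours()` returns elapsed hours since the series start;
#' `es_clock_hours()` returns the clock time of day in hours, in `[0, 24)`.
#'
#' @param x An [epoch_series].
#' @return Numeric (or POSIXct) vector, one element per epoch.
#' @export
es_times <- function(x) x$start + (seq_along(x$counts) - 1) * x$epoch_s

#' @rdname es_times
#' @export
es_hours <- function(x) (seq_along(x$counts) - 1) * x$epoch_s / 3600

#' @rdname es_times
#' @export
es_clock_hours <- function(x) {
  start_clock <- as.numeric(x$start - trunc(x$start, "days"), units = "hours")
  (start_clock + es_hours(x)) %% 24
}

#' Read and write epoch-level activity CSV
#'
#' The epoch dialect is `subject,session,timestamp,count` with ISO-8601
#' timestamps; epochs within a session must be regular. `read_epoch_csv()`
#' returns one [epoch_series] per subject-session pair.
#'
#' @param path CSV file path.
#' @return `read_epoch_csv()`: a list of [epoch_series]. `write_epoch_csv()`:
#'   the path, invisibly.
#' @export
read_epoch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "session", "timestamp", "count") %in% names(df)))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  out <- lapply(split(df, interaction(df$subject, df$session, drop = TRUE)), function(d) {
    d <- d[order(d$timestamp), ]
    steps <- as.numeric(diff(d$timestamp), units = "secs")
    if (length(steps) && (max(steps) - min(steps)) > 1e-6)
      stop("irregular epoch spacing for subject ", d$subject[1], " session ", d$session[1])
    epoch_series(d$count, epoch_s = if (length(steps)) steps[1] else 15,
                 start = d$timestamp[1], subject = d$subject[1], session = d$session[1])
  })
  unname(out)
}

#' @rdname read_epoch_csv
#' @param series A list of [epoch_series] (or a single one).
#' @export
write_epoch_csv <- function(series, path) {
  if (inherits(series, "epoch_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(subject = s$subject, session = s$session,
               timestamp = format(es_times(s), "%Y-%m-%dT%H:%M:%S"),
               count = s$counts)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
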