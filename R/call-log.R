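# Call-log handling: parsing, exclusion filtering, rate estimation and
# goodness-of-fit checks for the Markov assumptions (Poisson arrivals,
# exponential service).
#
# Exclusion rules: records lasting one minute or less (duration <= 60 s)
# and records lasting more than four hours (duration > 14,400 s) are
# removed from the *service-time* analysis; the arrival analysis keeps all
# records. Boundary handling: 60 s is excluded, 14,400 s is retained.

.SHORT_CUTOFF_S <- 60
.LONG_CUTOFF_S <- 14400

#' Construct a call log
#'
#' One row per emergency: start timestamp and duration in seconds. Records
#' are sorted by start time; the observation window defaults to the whole
#' days spanning the data.
#'
#' @param start_time `POSIXct` vector of call start times.
#' @param duration_seconds non-negative numeric vector, same length.
#' @param window length-2 `POSIXct` (start, end) observation window, or
#'   `NULL` to infer it from the data (midnight before the first record to
#'   midnight after the last).
#' @param provenance `"observed"` or `"synthetic"`; synthetic logs carry
#'   their generator seed in `attr(, "seed")`.
#' @return an object of class `call_log`: a data.frame with columns
#'   `start_time`, `duration_seconds` and attributes `window`,
#'   `provenance`.
#' @examples
#' call_log(as.POSIXct("2018-04-01 10:15:00", tz = "UTC"), 900)
#' @export
call_log <- function(start_time, duration_seconds, window = NULL,
                     provenance = c("observed", "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(start_time, "POSIXct"),
            length(start_time) == length(duration_seconds))
  if (any(is.na(duration_seconds)) || any(duration_seconds < 0))
    stop("durations must be non-negative and non-missing", call. = FALSE)
  ord <- order(start_time)
  df <- data.frame(start_time = start_time[ord],
                   duration_seconds = as.numeric(duration_seconds)[ord])
  if (is.null(window)) {
    if (nrow(df) == 0)
      stop("cannot infer a window from an empty log", call. = FALSE)
    lo <- trunc(min(df$start_time), "days")
    hi <- trunc(max(df$start_time), "days") + 86400
    window <- c(lo, hi)
  }
  window <- as.POSIXct(window, tz = "UTC")
  if (length(window) != 2L || is.na(window[1]) || is.na(window[2]) ||
      diff(as.numeric(window)) < 86400)
    stop("`window` must be two timestamps spanning at least one day",
         call. = FALSE)
  if (nrow(df) > 0 &&
      (min(df$start_time) < window[1] || max(df$start_time) >= window[2]))
    stop("records fall outside the observation window", call. = FALSE)
  structure(df, window = window, provenance = provenance,
            class = c("call_log", "data.frame"))
}

#' @export
print.call_log <- function(x, ...) {
  w <- attr(x, "window")
  days <- as.numeric(difftime(w[2], w[1], units = "days"))
  cat(sprintf("Call log (%s): %d records over %.1f days [%s .. %s)\n",
              attr(x, "provenance"), nrow(x), days,
              format(w[1], "%Y-%m-%d"), format(w[2], "%Y-%m-%d")))
  if (nrow(x) > 0) print.data.frame(head(x, 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Read a call log from a delimited text file
#'
#' Expects a CSV with header columns `start_time` (ISO-8601, parsed as
#' UTC) and `duration_seconds` (non-negative number). Malformed rows abort
#' with their line numbers; rows outside the window are dropped with a
#' message reporting the count.
#'
#' @param path file path.
#' @param window optional length-2 `POSIXct` observation window; records
#'   outside it are rejected (counted, not kept).
#' @param tz timezone for parsing, default UTC.
#' @return a [call_log()].
#' @export
load_call_log <- function(path, window = NULL, tz = "UTC") {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0) stop("empty call log: ", path, call. = FALSE)
  if (!all(c("start_time", "duration_seconds") %in% names(raw)))
    stop("call log needs columns `start_time` and `duration_seconds`",
         call. = FALSE)
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_character_, nrow(raw)), tz = tz)
  for (fmt in formats) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw$start_time[miss], fmt, tz = tz))
  }
  dur <- suppressWarnings(as.numeric(raw$duration_seconds))
  bad <- which(is.na(ts) | is.na(dur) | dur < 0)
  if (length(bad) > 0)
    stop("malformed call-log rows (file line numbers, header = line 1): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  if (!is.null(window)) {
    window <- as.POSIXct(window, tz = tz)
    outside <- ts < window[1] | ts >= window[2]
    if (any(outside))
      message(sum(outside), " record(s) outside the observation window dropped")
    ts <- ts[!outside]
    dur <- dur[!outside]
  }
  call_log(ts, dur, window = window)
}

#' Write a call log in the package's CSV dialect
#'
#' Columns `start_time` (ISO-8601, UTC) and `duration_seconds`; reading the
#' file back with [load_call_log()] reproduces the log.
#'
#' @param log a [call_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_call_log <- function(log, path) {
  stopifnot(inherits(log, "call_log"))
  out <- data.frame(
    start_time = format(log$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_seconds = log$duration_seconds)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the service-time exclusion rules
#'
#' Removes records of one minute or less (`<= 60` s; typically
#' mis-triggered or aborted contacts) and records above four hours
#' (`> 14,400` s) from the service-time analysis set. All records remain
#' available for arrival-rate analysis. The operation is idempotent and
#' independent of record order.
#'
#' @param log a [call_log()].
#' @return a list with `service_set` (a [call_log()] restricted to retained
#'   records) and `counts` (named integer vector: `n_total`,
#'   `n_excluded_short`, `n_excluded_long`, `n_retained`).
#' @examples
#' lg <- call_log(as.POSIXct("2018-04-01", tz = "UTC") + c(1, 2, 3) * 3600,
#'                c(30, 90, 15000))
#' apply_exclusions(lg)$counts
#' @export
apply_exclusions <- function(log) {
  stopifnot(inherits(log, "call_log"))
  short <- log$duration_seconds <= .SHORT_CUTOFF_S
  long <- log$duration_seconds > .LONG_CUTOFF_S
  keep <- !short & !long
  service <- structure(log[keep, , drop = FALSE],
                       window = attr(log, "window"),
                       provenance = attr(log, "provenance"),
                       class = c("call_log", "data.frame"))
  list(service_set = service,
       counts = c(n_total = nrow(log),
                  n_excluded_short = sum(short),
                  n_excluded_long = sum(long),
                  n_retained = sum(keep)))
}

#' Hour-of-day arrival profile of a log
#'
#' Counts calls by the local-clock hour of their start time, bins
#' `[h:00, h+1:00)`.
#'
#' @param log a [call_log()].
#' @return integer vector of length 24, named "0".."23".
#' @export
hourly_counts <- function(log) {
  stopifnot(inherits(log, "call_log"))
  h <- as.integer(format(log$start_time, "%H"))
  tabulate(h + 1L, nbins = 24L) |>
    stats::setNames(as.character(0:23))
}

#' Estimate queueing-model rates from a call log
#'
#' Derives the inputs of the M/M/k model: the overall arrival rate
#' (calls/h across the whole window), the peak-hour arrival rate
#' \eqn{\lambda} (calls/h during the busiest hour of day), and the service
#' rate \eqn{\mu} = 3600 / mean retained duration, after
#' [apply_exclusions()].
#'
#' @param log a non-empty [call_log()].
#' @param peak_hour hour of day (0-23) to use as the peak; `NULL` picks the
#'   hour with the most calls.
#' @return an object of class `rate_estimates`: list with
#'   `overall_arrival_rate`, `peak_hour`, `peak_arrival_rate`,
#'   `service_rate`, `mean_service_seconds`, `sd_service_seconds`,
#'   `n_total`, `n_excluded_short`, `n_excluded_long`, `days`,
#'   `hourly_counts`.
#' @export
estimate_rates <- function(log, peak_hour = NULL) {
  stopifnot(inherits(log, "call_log"))
  if (nrow(log) == 0) stop("empty call log", call. = FALSE)
  w <- attr(log, "window")
  days <- as.numeric(difftime(w[2], w[1], units = "days"))
  profile <- hourly_counts(log)
  if (is.null(peak_hour)) peak_hour <- which.max(profile) - 1L
  excl <- apply_exclusions(log)
  if (excl$counts[["n_retained"]] == 0)
    stop("no records remain after exclusion; cannot estimate the service rate",
         call. = FALSE)
  mean_s <- mean(excl$service_set$duration_seconds)
  structure(
    list(overall_arrival_rate = nrow(log) / (24 * days),
         peak_hour = as.integer(peak_hour),
         peak_arrival_rate = profile[[as.character(peak_hour)]] / days,
         service_rate = 3600 / mean_s,
         mean_service_seconds = mean_s,
         sd_service_seconds = sd(excl$service_set$duration_seconds),
         n_total = excl$counts[["n_total"]],
         n_excluded_short = excl$counts[["n_excluded_short"]],
         n_excluded_long = excl$counts[["n_excluded_long"]],
         days = days,
         hourly_counts = profile),
    class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat("Rate estimates\n")
  cat(sprintf("  %d calls over %.1f days (%.2f/day); excluded: %d short, %d long\n",
              x$n_total, x$days, x$n_total / x$days,
              x$n_excluded_short, x$n_excluded_long))
  cat(sprintf("  overall lambda: %.3f calls/h; peak hour %02d:00 lambda: %.3f calls/h\n",
              x$overall_arrival_rate, x$peak_hour, x$peak_arrival_rate))
  cat(sprintf("  mu: %.3f calls/h (mean service %.0f s, sd %.0f s)\n",
              x$service_rate, x$mean_service_seconds, x$sd_service_seconds))
  invisible(x)
}

# Chi-square statistic of observed count frequencies against a discrete
# pmf, pooling the upper tail so every expected cell is >= 5.
.chi2_counts <- function(obs_counts, pmf, n_estimated) {
  n <- length(obs_counts)
  mx <- max(obs_counts)
  freq <- tabulate(obs_counts + 1L, nbins = mx + 2L) # values 0..mx, then >mx
  expected <- n * c(pmf(0:mx), 1 - sum(pmf(0:mx)))
  # pool cells from the right until each expected >= 5
  while (length(expected) > 2L && expected[length(expected)] < 5) {
    k <- length(expected)
    expected[k - 1L] <- expected[k - 1L] + expected[k]
    freq[k - 1L] <- freq[k - 1L] + freq[k]
    expected <- expected[-k]; freq <- freq[-k]
  }
  stat <- sum((freq - expected)^2 / expected)
  df <- max(1L, length(expected) - 1L - n_estimated)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Goodness-of-fit tests for the Markov assumptions
#'
#' Tests whether per-interval call counts are Poisson (chi-square on the
#' frequency table of counts, mean estimated from the data, one degree of
#' freedom deducted) and whether retained service durations are exponential
#' (chi-square over equal-probability bins of the fitted exponential, and a
#' Kolmogorov-Smirnov test against the fitted rate).
#'
#' Because [apply_exclusions()] removes durations of 60 s or less, the
#' retained sample is left-truncated at 60 s. Under the exponential null
#' the excess `duration - 60` is again exponential with the same rate
#' (memorylessness), so both duration tests are applied to the excess over
#' the cutoff; without this shift an exactly exponential world would be
#' rejected for large samples. The KS p-value is additionally conservative
#' because the rate is estimated from the same data (composite null); it
#' is a diagnostic, not a calibrated error rate.
#'
#' @param log a [call_log()] with at least 30 records.
#' @param interval_hours width of the counting interval for the Poisson
#'   test, default 1 hour.
#' @param n_bins number of equal-probability bins for the exponential
#'   chi-square, default 10.
#' @return a list with `poisson_chi2`, `poisson_df`, `poisson_p`,
#'   `exp_chi2`, `exp_df`, `exp_p`, `exp_ks`, `exp_ks_p`.
#' @export
goodness_of_fit <- function(log, interval_hours = 1, n_bins = 10L) {
  stopifnot(inherits(log, "call_log"))
  if (nrow(log) < 30)
    stop("need at least 30 records for goodness-of-fit tests", call. = FALSE)
  w <- attr(log, "window")
  total_h <- as.numeric(difftime(w[2], w[1], units = "hours"))
  n_int <- floor(total_h / interval_hours)
  idx <- floor(as.numeric(difftime(log$start_time, w[1], units = "hours")) /
                 interval_hours)
  counts <- tabulate(idx[idx < n_int] + 1L, nbins = n_int)
  lam_hat <- mean(counts)
  pois <- .chi2_counts(counts, function(x) stats::dpois(x, lam_hat), 1L)

  durs <- apply_exclusions(log)$service_set$duration_seconds
  if (length(durs) < 30)
    stop("need at least 30 retained durations for the exponential tests",
         call. = FALSE)
  durs <- durs - .SHORT_CUTOFF_S # memorylessness: excess over the cutoff
  rate_hat <- 1 / mean(durs)
  # equal-probability bins under the fitted exponential
  edges <- qexp(seq(0, 1, length.out = n_bins + 1L), rate = rate_hat)
  obs <- tabulate(findInterval(durs, edges, rightmost.closed = TRUE),
                  nbins = n_bins)
  expd <- rep(length(durs) / n_bins, n_bins)
  exp_stat <- sum((obs - expd)^2 / expd)
  exp_df <- n_bins - 1L - 1L
  ks <- suppressWarnings(ks.test(durs, "pexp", rate = rate_hat))
  list(poisson_chi2 = pois$stat, poisson_df = pois$df, poisson_p = pois$p,
       exp_chi2 = exp_stat, exp_df = exp_df,
       exp_p = pchisq(exp_stat, exp_df, lower.tail = FALSE),
       exp_ks = unname(ks$statistic), exp_ks_p = ks$p.value)
}
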