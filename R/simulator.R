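# Discrete-event M/M/k FIFO simulator (brute-force oracle for the analytic
# formulas) and a synthetic call-log generator with an hour-of-day arrival
# intensity.
#
# RNG discipline: the user seed spawns independent substreams for the
# arrival and the service process, so changing service parameters never
# perturbs the arrival sequence of a scenario.

.substreams <- function(seed, n = 2L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Default hour-of-day arrival intensity [calls/h], hours 0..23. Shaped after
# the observed profile of a rural teleemergency office: busiest 08:00-13:00,
# absolute peak 10:00-11:00 at 0.27 calls/h, 0.186 calls/h at 07:00, and a
# daily total of 4.14 calls.
.default_hourly_rates <- c(rep(0.12, 6), 0.144, 0.186,
                           0.24, 0.25, 0.27, 0.26, 0.25, 0.22,
                           0.20, 0.19, 0.19, 0.18, 0.17, 0.16,
                           0.15, 0.13, 0.12, 0.11)

#' Hour-of-day arrival intensity profile
#'
#' 24 hourly arrival rates (calls/h) describing a non-homogeneous Poisson
#' arrival process. The default emulates the observed office profile: peak
#' 0.27 calls/h between 10:00 and 11:00, elevated rates 08:00-13:00, and a
#' mean of 4.14 calls per day.
#'
#' @param hourly_rates numeric vector of 24 non-negative rates.
#' @return an object of class `intensity_profile` with fields
#'   `hourly_rates` and `daily_mean` (their sum).
#' @examples
#' intensity_profile()$daily_mean # 4.14
#' @export
intensity_profile <- function(hourly_rates = .default_hourly_rates) {
  if (length(hourly_rates) != 24L || any(is.na(hourly_rates)) ||
      any(hourly_rates < 0))
    stop("`hourly_rates` must be 24 non-negative values", call. = FALSE)
  structure(list(hourly_rates = as.numeric(hourly_rates),
                 daily_mean = sum(hourly_rates)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Hourly arrival intensity (daily mean %.2f calls/day, peak %.3g calls/h at %02d:00)\n",
              x$daily_mean, max(x$hourly_rates),
              which.max(x$hourly_rates) - 1L))
  invisible(x)
}

# Evaluate a piecewise-constant cumulative function. `starts` are the
# left endpoints of intervals with values `vals` (per unit time), `cum`
# the cumulative integral at each start.
.cum_at <- function(t, starts, cum, vals) {
  j <- findInterval(t, starts)
  cum[j] + vals[j] * (t - starts[j])
}

#' Simulate an M/M/k FIFO queue
#'
#' Event-driven simulation with exponential inter-arrivals (rate
#' \eqn{\lambda}), exponential service times (rate \eqn{\mu}), \eqn{k = mn}
#' channels, an unbounded FIFO queue and an empty start. The first
#' `warmup_fraction` of the horizon is discarded before computing time
#' averages. Two empirical overburdening statistics are reported, because
#' their analytic counterparts differ: the fraction of *time* with more
#' than \eqn{k} calls in the system (compare
#' [overburdening_probability()]) and the fraction of *arrivals* delayed,
#' i.e. finding all channels busy (compare
#' [erlang_c_waiting_probability()], by PASTA). Batch-means standard
#' errors accompany both.
#'
#' @param params a [queue_parameters()] object. Unstable parameters
#'   (\eqn{\rho \ge k}) are accepted but flagged; their statistics diverge
#'   with the horizon.
#' @param horizon_hours simulated time span (> 0).
#' @param seed integer RNG seed; results are reproducible per
#'   (params, horizon, seed).
#' @param warmup_fraction fraction of the horizon discarded as warm-up.
#' @param n_batches batches for the batch-means standard errors.
#' @return an object of class `simulation_result`; see Details. Fields:
#'   `n_arrivals`, `n_delayed`, `p_state_gt_k` (+`_se`),
#'   `p_arrival_delayed` (+`_se`), `occupancy_histogram` (time-weighted
#'   state probabilities, named by state) with `occupancy_se` (per-state
#'   batch-means errors), `mean_wait_seconds`,
#'   `mean_number_in_system`, `seed`, `horizon_hours`, `stable`.
#' @examples
#' simulate_queue(queue_parameters(0.54, 2.53), horizon_hours = 1e4, seed = 1)
#' @export
simulate_queue <- function(params, horizon_hours, seed,
                           warmup_fraction = 0.05, n_batches = 20L) {
  stopifnot(inherits(params, "queue_parameters"))
  if (!is.numeric(horizon_hours) || horizon_hours <= 0)
    stop("`horizon_hours` must be positive", call. = FALSE)
  lambda <- params$arrival_rate
  mu <- params$service_rate
  k <- params$channels
  stable <- params$traffic_density < k
  if (!stable)
    warning("unstable parameters (rho >= k): statistics diverge with horizon")
  seeds <- .substreams(seed, 2L)
  H <- horizon_hours
  warm <- warmup_fraction * H

  # arrivals: homogeneous Poisson process on (0, H]
  arr <- numeric(0)
  if (lambda > 0) {
    set.seed(seeds[1])
    t_last <- 0
    repeat {
      need <- ceiling(lambda * (H - t_last) + 6 * sqrt(lambda * H) + 50)
      arr <- c(arr, t_last + cumsum(rexp(need, lambda)))
      t_last <- arr[length(arr)]
      if (t_last > H) break
    }
    arr <- arr[arr <= H]
  }
  n <- length(arr)
  if (n == 0) {
    return(structure(list(
      n_arrivals = 0L, n_delayed = 0L,
      p_state_gt_k = 0, p_state_gt_k_se = 0,
      p_arrival_delayed = NA_real_, p_arrival_delayed_se = NA_real_,
      occupancy_histogram = c(`0` = 1), occupancy_se = c(`0` = 0),
      mean_wait_seconds = NA_real_,
      mean_number_in_system = 0, seed = seed, horizon_hours = H,
      warmup_fraction = warmup_fraction, params = params, stable = stable),
      class = "simulation_result"))
  }
  set.seed(seeds[2])
  svc <- rexp(n, mu)

  starts <- mmk_service_starts(arr, svc, k)
  waits <- starts - arr
  dep <- starts + svc

  # state trajectory: +1 at each arrival, -1 at each departure before H
  ev_t <- c(arr, dep[dep <= H])
  ev_d <- c(rep(1L, n), rep(-1L, sum(dep <= H)))
  ord <- order(ev_t)
  t_sorted <- ev_t[ord]
  state <- cumsum(ev_d[ord])
  seg_start <- c(0, t_sorted)
  seg_state <- c(0L, state)
  seg_len <- c(t_sorted, H) - seg_start
  # time averages over [warm, H]
  clip <- pmax(0, pmin(seg_start + seg_len, H) - pmax(seg_start, warm))
  tot <- sum(clip)
  occ <- rowsum(clip, seg_state)
  occupancy <- stats::setNames(as.numeric(occ) / tot, rownames(occ))
  p_gt_k <- sum(clip[seg_state > k]) / tot
  mean_L <- sum(clip * seg_state) / tot

  # batch-means errors on [warm, H]: time fraction satisfying an indicator,
  # per batch, via the cumulative occupation time of the state path
  bounds <- seq(warm, H, length.out = n_batches + 1L)
  batch_se <- function(ind) {
    cum <- c(0, cumsum(ind * seg_len))[seq_along(seg_start)]
    frac <- diff(.cum_at(bounds, seg_start, cum, ind)) / diff(bounds)
    sd(frac) / sqrt(n_batches)
  }
  p_gt_k_se <- batch_se(as.numeric(seg_state > k))
  occupancy_se <- vapply(as.integer(names(occupancy)), function(s)
    batch_se(as.numeric(seg_state == s)), numeric(1))
  names(occupancy_se) <- names(occupancy)

  post <- arr >= warm
  delayed <- waits > 0
  n_post <- sum(post)
  if (n_post > 0) {
    p_delay <- mean(delayed[post])
    bidx <- findInterval(arr[post], bounds, rightmost.closed = TRUE)
    bfrac <- tapply(delayed[post], factor(bidx, levels = 1:n_batches), mean)
    bfrac <- bfrac[!is.na(bfrac)]
    p_delay_se <- if (length(bfrac) > 1) sd(bfrac) / sqrt(length(bfrac)) else NA_real_
    mean_wait <- mean(waits[post]) * 3600
  } else {
    p_delay <- NA_real_; p_delay_se <- NA_real_; mean_wait <- NA_real_
  }

  structure(list(
    n_arrivals = n, n_delayed = sum(delayed),
    p_state_gt_k = p_gt_k, p_state_gt_k_se = p_gt_k_se,
    p_arrival_delayed = p_delay, p_arrival_delayed_se = p_delay_se,
    occupancy_histogram = occupancy, occupancy_se = occupancy_se,
    mean_wait_seconds = mean_wait,
    mean_number_in_system = mean_L,
    seed = seed, horizon_hours = H, warmup_fraction = warmup_fraction,
    params = params, stable = stable),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("M/M/%d simulation: %g h horizon, seed %d%s\n",
              x$params$channels, x$horizon_hours, x$seed,
              if (x$stable) "" else " [UNSTABLE]"))
  cat(sprintf("  arrivals: %d (%d delayed)\n", x$n_arrivals, x$n_delayed))
  cat(sprintf("  P(state > k): %.5f (se %.2g); P(arrival delayed): %.5f (se %.2g)\n",
              x$p_state_gt_k, x$p_state_gt_k_se,
              x$p_arrival_delayed, x$p_arrival_delayed_se))
  cat(sprintf("  mean in system: %.4f; mean wait: %.1f s\n",
              x$mean_number_in_system, x$mean_wait_seconds))
  invisible(x)
}

#' Generate a synthetic call log
#'
#' Draws a call log with the statistical structure of the observed data:
#' non-homogeneous Poisson arrivals following an hour-of-day
#' [intensity_profile()] (simulated by thinning a homogeneous process at
#' the peak rate), exponential service durations with the given mean, a
#' planted fraction of very short records (1-60 s, emulating mis-triggered
#' contacts) and a rare fraction of over-four-hour records, so that the
#' exclusion rules of [apply_exclusions()] are exercised. Deterministic
#' per seed.
#'
#' @param profile an [intensity_profile()].
#' @param mean_service_seconds mean of the exponential service duration for
#'   regular calls; default 1477 s (24:37 min).
#' @param days number of days to simulate (>= 1).
#' @param short_call_fraction fraction of records replaced by 1-60 s
#'   durations; default 253/3019, the observed share.
#' @param long_call_fraction fraction replaced by > 4 h durations; default
#'   3/3019.
#' @param seed integer RNG seed.
#' @param start_date first day of the log (a `Date`).
#' @return a [call_log()] with `provenance = "synthetic"` and the seed in
#'   `attr(, "seed")`.
#' @examples
#' lg <- generate_synthetic_log(days = 30, seed = 1)
#' @export
generate_synthetic_log <- function(profile = intensity_profile(),
                                   mean_service_seconds = 1477,
                                   days = 730L,
                                   short_call_fraction = 253 / 3019,
                                   long_call_fraction = 3 / 3019,
                                   seed,
                                   start_date = as.Date("2018-04-01")) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (days < 1) stop("`days` must be >= 1", call. = FALSE)
  if (short_call_fraction + long_call_fraction >= 1)
    stop("planted fractions must sum to < 1", call. = FALSE)
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  window <- c(origin, origin + days * 86400)
  rates <- profile$hourly_rates
  rmax <- max(rates)
  if (rmax == 0) {
    warning("all-zero intensity profile: empty log")
    return(call_log(origin[0], numeric(0), window = window,
                    provenance = "synthetic"))
  }
  seeds <- .substreams(seed, 2L)
  H <- days * 24

  # homogeneous process at the peak rate, thinned by rate(hour)/rmax
  set.seed(seeds[1])
  t_last <- 0; arr <- numeric(0)
  repeat {
    need <- ceiling(rmax * (H - t_last) + 6 * sqrt(rmax * H) + 50)
    arr <- c(arr, t_last + cumsum(rexp(need, rmax)))
    t_last <- arr[length(arr)]
    if (t_last > H) break
  }
  arr <- arr[arr <= H]
  keep <- runif(length(arr)) < rates[floor(arr %% 24) + 1L] / rmax
  arr <- arr[keep]
  n <- length(arr)

  set.seed(seeds[2])
  dur <- rexp(n, 1 / mean_service_seconds)
  u <- runif(n)
  short <- u < short_call_fraction
  long <- !short & u < short_call_fraction + long_call_fraction
  dur[short] <- runif(sum(short), 1, 60)
  dur[long] <- .LONG_CUTOFF_S + rexp(sum(long), 1 / 3600)
  dur <- pmax(1, round(dur))

  lg <- call_log(origin + floor(arr * 3600), dur, window = window,
                 provenance = "synthetic")
  attr(lg, "seed") <- seed
  lg
}
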