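# Inverts the queueing model into staffing answers: how many doctors for a
# given fleet, how many ambulances per doctor count, and the full
# doctors-by-ambulances probability table.

#' Capacity-planning policy
#'
#' Bundles the assumptions under which staffing questions are answered:
#' the per-ambulance arrival rate (default 0.045 calls/h, the district rate
#' 0.27 spread over its 6 telemedical ambulances), the service rate, the
#' parallel-call limit per doctor, the tolerated overburdening probability
#' and the granularity of the ambulance search grid (default 6 ambulances,
#' one district-equivalent).
#'
#' @param per_ambulance_arrival_rate calls per hour contributed by one
#'   telemedical ambulance.
#' @param service_rate \eqn{\mu} in calls per hour; defaults to the
#'   effective preset, see [service_rate_preset()].
#' @param calls_per_doctor \eqn{m}.
#' @param max_overburdening tolerated probability that a call is put on
#'   hold, in (0, 1). Typical planning values: 0.05, 0.10, 0.20.
#' @param ambulance_step granularity of the ambulance grid (integer >= 1).
#' @return an object of class `capacity_policy`.
#' @examples
#' capacity_policy(max_overburdening = 0.05)
#' @export
capacity_policy <- function(per_ambulance_arrival_rate = 0.045,
                            service_rate = service_rate_preset("effective"),
                            calls_per_doctor = 2L,
                            max_overburdening = 0.05,
                            ambulance_step = 6L) {
  if (!is.numeric(max_overburdening) || is.na(max_overburdening) ||
      max_overburdening <= 0 || max_overburdening >= 1)
    stop("`max_overburdening` must lie strictly between 0 and 1",
         call. = FALSE)
  if (!is.numeric(per_ambulance_arrival_rate) ||
      per_ambulance_arrival_rate <= 0)
    stop("`per_ambulance_arrival_rate` must be positive", call. = FALSE)
  if (ambulance_step < 1 || ambulance_step != as.integer(ambulance_step))
    stop("`ambulance_step` must be a positive integer", call. = FALSE)
  if (service_rate <= 0) stop("`service_rate` must be positive", call. = FALSE)
  structure(
    list(per_ambulance_arrival_rate = per_ambulance_arrival_rate,
         service_rate = service_rate,
         calls_per_doctor = as.integer(calls_per_doctor),
         max_overburdening = max_overburdening,
         ambulance_step = as.integer(ambulance_step)),
    class = "capacity_policy")
}

#' @export
print.capacity_policy <- function(x, ...) {
  cat("Capacity policy\n")
  cat(sprintf("  per-ambulance rate: %g calls/h, service rate: %g calls/h\n",
              x$per_ambulance_arrival_rate, x$service_rate))
  cat(sprintf("  calls per doctor: %d, tolerated overburdening: %g%%, step: %d ambulances\n",
              x$calls_per_doctor, 100 * x$max_overburdening, x$ambulance_step))
  invisible(x)
}

#' Minimum number of doctors for a given total arrival rate
#'
#' Smallest \eqn{n \ge 1} whose overburdening probability does not exceed
#' the policy's tolerance. Found by upward scan; the probability is
#' strictly decreasing in the doctor count, so the answer is stable.
#'
#' @param total_arrival_rate total calls per hour offered to the office.
#' @param policy a [capacity_policy()].
#' @return integer count of doctors.
#' @examples
#' min_teds(240 * 0.045, capacity_policy(max_overburdening = 0.05)) # 4
#' @export
min_teds <- function(total_arrival_rate, policy = capacity_policy()) {
  stopifnot(inherits(policy, "capacity_policy"))
  if (total_arrival_rate < 0)
    stop("`total_arrival_rate` must be non-negative", call. = FALSE)
  n <- 1L
  while (.overburdening(total_arrival_rate, policy$service_rate,
                        policy$calls_per_doctor * n) >
         policy$max_overburdening)
    n <- n + 1L
  n
}

#' Maximum number of ambulances a staff of doctors can serve
#'
#' Largest multiple of the policy's `ambulance_step` whose overburdening
#' probability stays within tolerance, given `doctors` on duty. Returns 0
#' if even one step exceeds the tolerance.
#'
#' @param doctors number of doctors on duty (integer >= 1).
#' @param policy a [capacity_policy()].
#' @return integer ambulance count (a multiple of the step).
#' @examples
#' max_ambulances(1, capacity_policy(max_overburdening = 0.05)) # 36
#' @export
max_ambulances <- function(doctors, policy = capacity_policy()) {
  stopifnot(inherits(policy, "capacity_policy"))
  if (doctors < 1 || doctors != as.integer(doctors))
    stop("`doctors` must be a positive integer", call. = FALSE)
  k <- policy$calls_per_doctor * as.integer(doctors)
  a <- 0L
  repeat {
    nxt <- a + policy$ambulance_step
    p <- .overburdening(nxt * policy$per_ambulance_arrival_rate,
                        policy$service_rate, k)
    if (p > policy$max_overburdening) break
    a <- nxt
  }
  a
}

#' Overburdening probabilities over a doctors-by-ambulances grid
#'
#' Tabulates \eqn{P(i > k)} for every combination of doctor count and
#' ambulance count. Saturated cells are reported as probability 1.
#'
#' @param doctor_counts integer vector of doctor counts.
#' @param ambulance_grid integer vector of ambulance counts.
#' @param policy a [capacity_policy()] (its `max_overburdening` is not used
#'   here; rates and the per-doctor call limit are).
#' @return a data.frame with columns `doctors`, `ambulances`, `districts`
#'   (ambulances divided by the step) and `probability`, ordered by doctors
#'   then ambulances.
#' @examples
#' overburdening_table(1:2, c(6, 60, 114))
#' @export
overburdening_table <- function(doctor_counts = 1:6,
                                ambulance_grid = seq(6L, 510L, by = 6L),
                                policy = capacity_policy()) {
  stopifnot(inherits(policy, "capacity_policy"),
            length(doctor_counts) > 0, length(ambulance_grid) > 0)
  grid <- expand.grid(ambulances = as.integer(ambulance_grid),
                      doctors = as.integer(doctor_counts))
  grid$probability <- mapply(function(a, d)
    .overburdening(a * policy$per_ambulance_arrival_rate,
                   policy$service_rate, policy$calls_per_doctor * d),
    grid$ambulances, grid$doctors)
  grid$districts <- grid$ambulances / policy$ambulance_step
  grid[, c("doctors", "ambulances", "districts", "probability")]
}
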