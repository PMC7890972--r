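# Steady-state analytics of the M/M/k; infinity, FIFO queue.
#
# State probabilities follow the standard birth-death solution:
#   w_i = rho^i / i! * w_0                      for i < k
#   w_i = rho^i / (k! * k^(i-k)) * w_0          for i >= k
# with w_0 the normalizing constant. Poisson-term products rho^i/i! are
# accumulated iteratively (term_i = term_{i-1} * rho / i), never via
# factorial(), so large k does not overflow.

# Unnormalized Poisson terms rho^i/i!, i = 0..k, plus the normalizing
# constant; shared by all closed forms below. Assumes rho < k.
.mmk_terms <- function(rho, k) {
  terms <- numeric(k + 1L)
  terms[1L] <- 1
  if (k >= 1L)
    for (i in seq_len(k)) terms[i + 1L] <- terms[i] * rho / i
  r <- rho / k
  w0 <- 1 / (sum(terms[seq_len(k)]) + terms[k + 1L] / (1 - r))
  list(terms = terms, w0 = w0, r = r)
}

#' Steady-state distribution of the number of calls in the system
#'
#' Computes \eqn{w_0, \ldots, w_{imax}} for a stable M/M/k queue along with
#' the analytic mass of the geometric tail beyond `imax`. For \eqn{i \ge k}
#' the probabilities decay geometrically with ratio \eqn{\rho/k}, so the
#' remainder \eqn{\sum_{i > imax} w_i} has the closed form
#' \eqn{w_{imax} \cdot (\rho/k) / (1 - \rho/k)}.
#'
#' @param params a [queue_parameters()] object with \eqn{\rho < k}.
#' @param imax largest state to tabulate explicitly (`imax >= k`); defaults
#'   to `k + 25`.
#' @return An object of class `state_distribution`: list with
#'   `probabilities` (numeric vector, states `0:imax`), `tail_mass`, and
#'   `params`. Probabilities plus tail mass sum to one.
#' @examples
#' sd <- state_distribution(queue_parameters(0.27, 2.57))
#' sum(sd$probabilities) + sd$tail_mass # 1
#' @export
state_distribution <- function(params, imax = NULL) {
  stopifnot(inherits(params, "queue_parameters"))
  k <- params$channels
  rho <- params$traffic_density
  if (is.null(imax)) imax <- k + 25L
  if (imax < k) stop("`imax` must be at least k = ", k, call. = FALSE)
  if (rho >= k)
    stop("saturated system (rho >= k); no steady state exists. ",
         "Use overburdening_probability(), which returns 1 in saturation.",
         call. = FALSE)
  base <- .mmk_terms(rho, k)
  probs <- numeric(imax + 1L)
  probs[seq_len(k + 1L)] <- base$terms * base$w0
  if (imax > k)
    probs[(k + 2L):(imax + 1L)] <- probs[k + 1L] * base$r^seq_len(imax - k)
  tail_mass <- probs[imax + 1L] * base$r / (1 - base$r)
  structure(list(probabilities = probs, tail_mass = tail_mass,
                 params = params),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  k <- x$params$channels
  cat(sprintf("M/M/%d state distribution (states 0..%d, tail mass %.3g)\n",
              k, length(x$probabilities) - 1L, x$tail_mass))
  show <- head(x$probabilities, min(length(x$probabilities), k + 4L))
  names(show) <- paste0("w", seq_along(show) - 1L)
  print(round(show, 6))
  invisible(x)
}

# Fast scalar path used by the planner and solver: P(i > k) from (lambda,
# mu, k) without constructing parameter objects.
.overburdening <- function(lambda, mu, k) {
  rho <- lambda / mu
  if (rho >= k) return(1)
  if (lambda == 0) return(0)
  base <- .mmk_terms(rho, k)
  # P(i > k) = sum_{i>k} w_i = w_k * r/(1-r)
  base$w0 * base$terms[k + 1L] * base$r / (1 - base$r)
}

.erlang_c <- function(lambda, mu, k) {
  rho <- lambda / mu
  if (rho >= k) return(1)
  if (lambda == 0) return(0)
  base <- .mmk_terms(rho, k)
  # P(i >= k) = w_k / (1 - r)
  base$w0 * base$terms[k + 1L] / (1 - base$r)
}

#' Overburdening probability P(i > k)
#'
#' The service-level statistic of the model: the steady-state probability
#' that more than \eqn{k} calls are in the system,
#' \eqn{P(i > k) = 1 - \sum_{i=0}^{k} w_i}, i.e. at least one incoming call
#' is on hold. Note this is *not* the textbook Erlang-C delay probability
#' \eqn{P(i \ge k)}, which is available as
#' [erlang_c_waiting_probability()] and is always at least as large.
#' A saturated system (\eqn{\rho \ge k}) returns exactly 1: the office
#' fails to cover all incoming calls.
#'
#' @param params a [queue_parameters()] object.
#' @return a probability in \eqn{[0, 1]}.
#' @examples
#' # two districts (12 ambulances) on one doctor: 0.22%
#' overburdening_probability(queue_parameters(0.54, 2.53))
#' @export
overburdening_probability <- function(params) {
  stopifnot(inherits(params, "queue_parameters"))
  .overburdening(params$arrival_rate, params$service_rate, params$channels)
}

#' Erlang-C waiting probability P(i >= k)
#'
#' The textbook probability that an arriving call finds all \eqn{k}
#' channels busy and must wait. Provided alongside
#' [overburdening_probability()] because the two differ by exactly
#' \eqn{w_k}; the package's planning statistic is the latter.
#' Returns 1 in saturation.
#'
#' @param params a [queue_parameters()] object.
#' @return a probability in \eqn{[0, 1]}.
#' @examples
#' erlang_c_waiting_probability(queue_parameters(0.27, 2.57))
#' @export
erlang_c_waiting_probability <- function(params) {
  stopifnot(inherits(params, "queue_parameters"))
  .erlang_c(params$arrival_rate, params$service_rate, params$channels)
}

#' Solve for the arrival rate giving a target overburdening probability
#'
#' Inverts the monotone map \eqn{\lambda \mapsto P(i > k)} by bisection on
#' the bracket \eqn{(0, k\mu)}, to absolute tolerance `tol` on
#' \eqn{\lambda}. Used, e.g., to ask how high the call volume may grow
#' before 10 percent of calls are put on hold.
#'
#' @param target_probability desired overburdening probability, in (0, 1).
#' @param service_rate \eqn{\mu} in calls per hour.
#' @param calls_per_doctor \eqn{m}.
#' @param doctors \eqn{n}.
#' @param tol absolute tolerance on the returned rate.
#' @return the arrival rate \eqn{\lambda} in calls per hour.
#' @examples
#' solve_arrival_rate(0.10, 2.53) # about 2.092
#' @export
solve_arrival_rate <- function(target_probability, service_rate,
                               calls_per_doctor = 2L, doctors = 1L,
                               tol = 1e-9) {
  if (!is.numeric(target_probability) || length(target_probability) != 1L ||
      is.na(target_probability) ||
      target_probability <= 0 || target_probability >= 1)
    stop("`target_probability` must lie strictly between 0 and 1",
         call. = FALSE)
  k <- as.integer(calls_per_doctor) * as.integer(doctors)
  lo <- 0
  hi <- k * service_rate
  f <- function(l) .overburdening(l, service_rate, k) - target_probability
  # P is 0 at lambda -> 0+ and -> 1 at lambda -> k*mu, so the bracket always
  # holds for targets in (0, 1); bisect until the bracket width is below tol.
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
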