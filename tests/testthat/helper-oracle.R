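# Independent brute-force oracle for the M/M/k steady state: evaluate the
# unnormalized birth-death terms in log space up to a large cutoff and
# normalize by the truncated sum. Shares no code with the package's
# closed forms.
oracle_state_probs <- function(lambda, mu, k, imax = 1e4) {
  if (lambda == 0) return(c(1, rep(0, imax)))
  rho <- lambda / mu
  i <- 0:imax
  logw <- ifelse(i < k,
                 i * log(rho) - lgamma(i + 1),
                 i * log(rho) - lgamma(k + 1) - (i - k) * log(k))
  w <- exp(logw - max(logw))
  w / sum(w)
}

oracle_overburdening <- function(lambda, mu, k, imax = 1e4) {
  w <- oracle_state_probs(lambda, mu, k, imax)
  sum(w[-(1:(k + 1))])
}

oracle_erlang_c <- function(lambda, mu, k, imax = 1e4) {
  w <- oracle_state_probs(lambda, mu, k, imax)
  sum(w[-(1:k)])
}

# Random stable parameter sets under a fixed seed, used by property tests.
stable_param_grid <- function(n_sets, seed = 4711) {
  set.seed(seed)
  data.frame(
    lambda = runif(n_sets, 0.01, 8),
    mu = runif(n_sets, 0.5, 4),
    m = sample(1:3, n_sets, replace = TRUE),
    n = sample(1:5, n_sets, replace = TRUE)
  ) |> subset(lambda / mu < 0.95 * m * n)
}

# Minimal call log: durations at given hour offsets (possibly > 24, to
# reach later days) from midnight UTC on the first window day.
make_log <- function(durations, hours = NULL, days = 1,
                     origin = as.POSIXct("2018-04-01", tz = "UTC")) {
  n <- length(durations)
  if (is.null(hours)) hours <- seq(0, days * 24 - 0.5, length.out = n)
  call_log(origin + hours * 3600, durations,
           window = c(origin, origin + days * 86400))
}
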