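test_that("traffic density is the plain ratio and validates its inputs", {
  expect_equal(traffic_density(0, 2.53), 0)
  expect_equal(traffic_density(2.53, 2.53), 1)
  expect_equal(traffic_density(0.27, 2.57), 0.27 / 2.57)
  expect_error(traffic_density(1, 0), "positive")
  expect_error(traffic_density(-1, 2), "non-negative")
})

test_that("queue_parameters derives k and rho and rejects bad input", {
  p <- queue_parameters(0.27, 2.57, doctors = 3, calls_per_doctor = 2)
  expect_s3_class(p, "queue_parameters")
  expect_identical(p$channels, 6L)
  expect_equal(p$traffic_density, 0.27 / 2.57)
  expect_error(queue_parameters(-1, 2), "non-negative")
  expect_error(queue_parameters(1, 0), "positive")
  expect_error(queue_parameters(1, 2, doctors = 0), "integer")
  expect_error(queue_parameters(1, 2, calls_per_doctor = 1.5), "integer")
})

test_that("state distribution matches the M/M/1 closed form", {
  p <- queue_parameters(0.5, 1, doctors = 1, calls_per_doctor = 1)
  sd1 <- state_distribution(p, imax = 30)
  expect_equal(sd1$probabilities, (1 - 0.5) * 0.5^(0:30), tolerance = 1e-12)
})

test_that("state distribution handles the empty system and saturation", {
  p0 <- queue_parameters(0, 2.53)
  sd0 <- state_distribution(p0)
  expect_equal(sd0$probabilities[1], 1)
  expect_equal(sum(sd0$probabilities[-1]), 0)
  expect_equal(sd0$tail_mass, 0)
  expect_error(state_distribution(queue_parameters(5.13, 2.53)), "saturated")
  expect_error(state_distribution(queue_parameters(0.27, 2.53), imax = 1),
               "imax")
})

test_that("w0 evaluates to 0.9002 with the printed inputs", {
  # the study prints 89.97% here; both presets give a different recomputed
  # value (documented non-reproduction)
  w0 <- state_distribution(queue_parameters(0.27, 2.57))$probabilities[1]
  expect_equal(w0, 0.9001848, tolerance = 1e-6)
  w0e <- state_distribution(queue_parameters(0.27, 2.53))$probabilities[1]
  expect_equal(w0e, 0.8986867, tolerance = 1e-6)
})

test_that("probabilities normalize to one with the analytic tail", {
  grid <- stable_param_grid(40)
  for (j in seq_len(nrow(grid))) {
    p <- queue_parameters(grid$lambda[j], grid$mu[j],
                          doctors = grid$n[j],
                          calls_per_doctor = grid$m[j])
    sdj <- state_distribution(p, imax = p$channels + sample(0:40, 1))
    expect_equal(sum(sdj$probabilities) + sdj$tail_mass, 1,
                 tolerance = 1e-12)
    expect_true(all(sdj$probabilities >= 0 & sdj$probabilities <= 1))
    # geometric decay with ratio rho/k beyond k
    k <- p$channels
    pr <- sdj$probabilities
    if (length(pr) > k + 2 && pr[k + 2] > 0)
      expect_equal(pr[k + 3] / pr[k + 2], p$traffic_density / k,
                   tolerance = 1e-9)
  }
})

test_that("overburdening reproduces the published series and saturation", {
  ob <- function(lam, mu) overburdening_probability(queue_parameters(lam, mu))
  expect_equal(ob(0.54, 2.53), 0.0022, tolerance = 5e-3)
  expect_equal(round(100 * ob(4.05, 2.53), 2), 56.96)
  expect_identical(ob(5.13, 2.53), 1) # rho >= k: saturated
  expect_identical(ob(0, 2.53), 0)
})

test_that("overburdening and Erlang-C agree with the brute-force oracle", {
  grid <- stable_param_grid(30)
  expect_gte(nrow(grid), 20)
  for (j in seq_len(nrow(grid))) {
    k <- grid$m[j] * grid$n[j]
    p <- queue_parameters(grid$lambda[j], grid$mu[j],
                          doctors = grid$n[j],
                          calls_per_doctor = grid$m[j])
    expect_equal(overburdening_probability(p),
                 oracle_overburdening(grid$lambda[j], grid$mu[j], k),
                 tolerance = 1e-10)
    expect_equal(erlang_c_waiting_probability(p),
                 oracle_erlang_c(grid$lambda[j], grid$mu[j], k),
                 tolerance = 1e-10)
  }
})

test_that("M/M/1 closed forms are exact and the statistics are ordered", {
  for (rho in c(0.1, 0.5, 0.9)) {
    p <- queue_parameters(rho, 1, doctors = 1, calls_per_doctor = 1)
    expect_equal(overburdening_probability(p), rho^2, tolerance = 1e-14)
    expect_equal(erlang_c_waiting_probability(p), rho, tolerance = 1e-14)
  }
  grid <- stable_param_grid(30, seed = 99)
  for (j in seq_len(nrow(grid))) {
    p <- queue_parameters(grid$lambda[j], grid$mu[j],
                          doctors = grid$n[j],
                          calls_per_doctor = grid$m[j])
    expect_lte(overburdening_probability(p),
               erlang_c_waiting_probability(p))
  }
})

test_that("Erlang-C matches the frozen closed-form example", {
  # oracle_erlang_c(0.27, 2.57, 2) = 0.005243209
  expect_equal(erlang_c_waiting_probability(queue_parameters(0.27, 2.57)),
               0.005243209, tolerance = 1e-7)
  expect_identical(erlang_c_waiting_probability(queue_parameters(0, 2.57)), 0)
  expect_identical(erlang_c_waiting_probability(queue_parameters(6, 2.53)), 1)
})

test_that("overburdening is monotone in lambda, mu and doctors", {
  lam <- seq(0.1, 4.9, by = 0.4)
  pr <- vapply(lam, function(l)
    overburdening_probability(queue_parameters(l, 2.53)), numeric(1))
  expect_true(all(diff(pr) > 0))
  mus <- seq(2.6, 5, by = 0.2)
  pr <- vapply(mus, function(m)
    overburdening_probability(queue_parameters(4, m)), numeric(1))
  expect_true(all(diff(pr) < 0))
  pr <- vapply(1:6, function(n)
    overburdening_probability(queue_parameters(3, 2.53, doctors = n)),
    numeric(1))
  expect_true(all(diff(pr) < 0))
})

test_that("solve_arrival_rate inverts the forward map", {
  lam10 <- solve_arrival_rate(0.10, 2.53)
  expect_equal(lam10, 2.092, tolerance = 1e-4)
  expect_equal(
    overburdening_probability(queue_parameters(lam10, 2.53)), 0.10,
    tolerance = 1e-8)
  # inverse of the published 56.96% forward computation
  expect_equal(solve_arrival_rate(0.569607, 2.53), 4.05, tolerance = 1e-4)
  # round trip on assorted targets and staffing levels
  for (target in c(0.001, 0.05, 0.5, 0.95)) {
    lam <- solve_arrival_rate(target, 2.53, doctors = 3)
    expect_equal(overburdening_probability(
      queue_parameters(lam, 2.53, doctors = 3)), target, tolerance = 1e-7)
  }
  expect_lt(solve_arrival_rate(1e-8, 2.53), 1e-2)
  expect_error(solve_arrival_rate(0, 2.53), "between 0 and 1")
  expect_error(solve_arrival_rate(1, 2.53), "between 0 and 1")
})
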