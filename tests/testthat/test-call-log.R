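test_that("call_log sorts records and validates window and durations", {
  origin <- as.POSIXct("2018-04-01", tz = "UTC")
  lg <- call_log(origin + c(7200, 3600, 10800), c(100, 200, 300))
  expect_s3_class(lg, "call_log")
  expect_true(!is.unsorted(lg$start_time))
  expect_identical(lg$duration_seconds, c(200, 100, 300))
  expect_error(call_log(origin, -5), "non-negative")
  expect_error(call_log(origin, 10, window = c(origin, origin + 3600)),
               "at least one day")
  expect_error(call_log(origin + 90000, 10,
                        window = c(origin, origin + 86400)),
               "outside the observation window")
})

test_that("write/load round-trips a log and rejects malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  lg <- generate_synthetic_log(days = 14, seed = 5)
  write_call_log(lg, path)
  back <- load_call_log(path, window = attr(lg, "window"))
  expect_equal(back$start_time, lg$start_time)
  expect_equal(back$duration_seconds, lg$duration_seconds)

  writeLines(c("start_time,duration_seconds",
               "2018-04-01T10:00:00,120",
               "2018-04-01T11:00:00,-4",
               "not-a-date,60"), path)
  expect_error(load_call_log(path), "line numbers.*3, 4")
  writeLines("start_time,duration_seconds", path)
  expect_error(load_call_log(path), "empty")
  writeLines(c("a,b", "1,2"), path)
  expect_error(load_call_log(path), "columns")
})

test_that("rows outside a supplied window are dropped with a count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start_time,duration_seconds",
               "2018-03-31T23:00:00,100",
               "2018-04-01T10:00:00,120"), path)
  origin <- as.POSIXct("2018-04-01", tz = "UTC")
  expect_message(
    lg <- load_call_log(path, window = c(origin, origin + 86400)),
    "1 record")
  expect_identical(nrow(lg), 1L)
})

test_that("exclusion rules: one minute or less out, four hours out", {
  lg <- make_log(c(30, 90, 15000), hours = c(1, 2, 3))
  ex <- apply_exclusions(lg)
  expect_identical(ex$service_set$duration_seconds, 90)
  expect_identical(ex$counts[["n_excluded_short"]], 1L)
  expect_identical(ex$counts[["n_excluded_long"]], 1L)
  # boundaries: exactly 60 s is excluded, exactly 4 h is retained
  bd <- apply_exclusions(make_log(c(60, 61, 14400, 14401), hours = 1:4))
  expect_identical(bd$service_set$duration_seconds, c(61, 14400))
  # identity on clean logs, and idempotence
  clean <- make_log(c(61, 1000, 14400), hours = 1:3)
  ex1 <- apply_exclusions(clean)
  expect_identical(nrow(ex1$service_set), 3L)
  ex2 <- apply_exclusions(ex1$service_set)
  expect_identical(ex2$counts[["n_retained"]], 3L)
})

test_that("planted short calls are excluded at the expected rate", {
  lg <- generate_synthetic_log(days = 400, short_call_fraction = 0.05,
                               seed = 17)
  ex <- apply_exclusions(lg)
  n <- ex$counts[["n_total"]]
  # planted 5% plus the exponential mass below 60 s
  p_expect <- 0.05 + (1 - 0.05 - 3 / 3019) * stats::pexp(60, 1 / 1477)
  phat <- ex$counts[["n_excluded_short"]] / n
  expect_lt(abs(phat - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("rate estimates: trivial logs behave as stated", {
  # uniform one-call-per-hour log: peak rate equals overall rate
  lg <- make_log(rep(1000, 48), hours = seq(0.5, 47.5, by = 1), days = 2)
  est <- estimate_rates(lg)
  expect_equal(est$overall_arrival_rate, 1)
  expect_equal(est$peak_arrival_rate, 1)
  # single-day log with calls only during 10:xx
  lg10 <- make_log(rep(500, 3), hours = c(10.1, 10.5, 10.9))
  expect_identical(estimate_rates(lg10)$peak_hour, 10L)
  expect_equal(estimate_rates(lg10)$service_rate, 3600 / 500)
  # estimates are invariant to record shuffling (sorting is internal)
  origin <- as.POSIXct("2018-04-01", tz = "UTC")
  set.seed(1)
  tt <- origin + runif(50, 0, 86400 - 1)
  dd <- runif(50, 100, 2000)
  sh <- sample(50)
  w <- c(origin, origin + 86400)
  e1 <- estimate_rates(call_log(tt, dd, window = w))
  e2 <- estimate_rates(call_log(tt[sh], dd[sh], window = w))
  expect_equal(e1[c("overall_arrival_rate", "peak_arrival_rate",
                    "service_rate")],
               e2[c("overall_arrival_rate", "peak_arrival_rate",
                    "service_rate")])
  # all records excluded -> no service rate
  expect_error(estimate_rates(make_log(c(10, 20), hours = 1:2)),
               "no records remain")
})

test_that("rates are recovered from a long synthetic log", {
  lg <- generate_synthetic_log(days = 700, seed = 20180401)
  est <- estimate_rates(lg, peak_hour = 10)
  expect_lt(abs(est$peak_arrival_rate - 0.27) / 0.27, 0.10)
  expect_lt(abs(est$service_rate - 3600 / 1477) / (3600 / 1477), 0.06)
  expect_lt(abs(est$overall_arrival_rate - 4.14 / 24) / (4.14 / 24), 0.05)
})

test_that("exponential GOF is calibrated on exponential service times", {
  origin <- as.POSIXct("2018-04-01", tz = "UTC")
  set.seed(2025)
  seeds <- sample.int(1e6, 100)
  ok <- vapply(seeds, function(s) {
    set.seed(s)
    n <- 2000
    tt <- origin + sort(runif(n, 0, 100 * 86400 - 1))
    dd <- 60 + rexp(n, 1 / 1477) # all retained; excess is exponential
    lg <- call_log(tt, dd, window = c(origin, origin + 100 * 86400))
    goodness_of_fit(lg)$exp_ks_p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("constant service times are rejected as exponential", {
  lg <- make_log(rep(900, 200), hours = seq(0.1, 23.9, length.out = 200))
  gof <- goodness_of_fit(lg)
  expect_lt(gof$exp_p, 0.01)
  expect_lt(gof$exp_ks_p, 0.01)
})

test_that("Poisson GOF holds its size on homogeneous Poisson arrivals", {
  origin <- as.POSIXct("2018-04-01", tz = "UTC")
  days <- 60
  pvals <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    gaps <- rexp(days * 24 * 2, 1) # rate 1 call/h
    tt <- cumsum(gaps)
    tt <- tt[tt < days * 24]
    lg <- call_log(origin + tt * 3600, rep(1000, length(tt)),
                   window = c(origin, origin + days * 86400))
    goodness_of_fit(lg)$poisson_p
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.30)
  expect_lt(mean(pvals), 0.70)
})

test_that("goodness_of_fit refuses tiny samples", {
  expect_error(goodness_of_fit(make_log(rep(100, 5), hours = 1:5)),
               "at least 30")
})
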