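test_that("a CV = 0 cohort row equals the typical-patient trough series", {
  cal <- fixture_calendar()
  spec <- arm_spec("A", "EM", "control")
  protocol <- build_protocol(spec, cal)
  pop <- sample_population(population_spec(1, "EM", 0, 0, seed = 1),
                           fixture_network(), theta = 1)
  tr <- run_arm(protocol, pop)
  ts <- pk_simulate(fixture_network(), "EM", protocol,
                    horizon = attr(protocol, "horizon_day"),
                    sample_times = 0:(attr(protocol, "horizon_day") - 1))
  expect_equal(dim(tr), c(1, 91, 4))
  expect_equal(tr[1, , ], ts$conc, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("doubling the protocol doses doubles every trough", {
  cal <- fixture_calendar()
  pop <- sample_population(population_spec(4, "IM", 0.3, 0.2, seed = 3),
                           fixture_network(), theta = 0.5)
  p1 <- build_protocol(arm_spec("B", "IM", "case", 2), cal)
  p2 <- p1
  p2$amount <- p1$amount * 2
  tr1 <- run_arm(p1, pop)
  tr2 <- run_arm(p2, pop)
  expect_equal(unclass(tr2), 2 * unclass(tr1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("percentile series follow the sort-based quantile oracle", {
  cal <- fixture_calendar()
  pop <- sample_population(population_spec(30, "EM", 0.4, 0.2, seed = 8),
                           fixture_network(), theta = 1)
  tr <- run_arm(build_protocol(arm_spec("A", "EM", "control"), cal), pop)
  mp <- median_percentiles(tr, "END")
  for (d in c(5, 40, 91)) {
    x <- tr[, d, "END"]
    expect_equal(mp$p5[d], naive_quantile(x, 0.05))
    expect_equal(mp$p50[d], naive_quantile(x, 0.50))
    expect_equal(mp$p95[d], naive_quantile(x, 0.95))
  }

  # degenerate cases: identical rows collapse all bands onto the median
  trc <- tr
  for (i in seq_len(dim(tr)[1])) trc[i, , ] <- tr[1, , ]
  mpc <- median_percentiles(trc, "END")
  expect_equal(mpc$p5, mpc$p95)

  # five constant patients 1..5 give median 3 everywhere
  fake <- array(rep(1:5, times = 10 * 4), dim = c(5, 10, 4),
                dimnames = list(NULL, NULL, c("TAM", "NDM", "4OH", "END")))
  class(fake) <- "trough_matrix"
  mpf <- median_percentiles(fake, "TAM")
  expect_true(all(mpf$p50 == 3))
  fake1 <- array(1, dim = c(1, 10, 4),
                 dimnames = list(NULL, NULL, c("TAM", "NDM", "4OH", "END")))
  class(fake1) <- "trough_matrix"
  expect_error(median_percentiles(fake1, "TAM"), "2 patients")
})

test_that("the crossing rule matches hand constructions and a brute-force scan", {
  # constantly above the benchmark: control achieves on day 1
  s <- rep(10, 50)
  expect_equal(time_to_target(s, 5, "control")$day, 1)
  # saturating series b * (1 - 2^(-d/h)): analytic control crossing day
  h <- 9; b <- 20; eps <- 0.01
  d <- 1:400
  s <- b * (1 - 2^(-d / h))
  expect_equal(time_to_target(s, b, "control", eps = eps)$day,
               ceiling(h * log2(1 / eps)))
  # the same series never strictly exceeds its own asymptote: case censors
  res <- time_to_target(s, b, "case")
  expect_true(res$censored)
  expect_equal(res$label, "> 400")
  # case rule reports the day before the strict exceedance
  s2 <- c(1, 2, 3, 21, 22)
  expect_equal(time_to_target(s2, 20, "case")$day, 3)
  # start_day offsets and censor limits are honoured
  expect_equal(time_to_target(c(0, 0, 0, 6, 7), 5, "control",
                              start_day = 3)$day, 2)
  expect_true(time_to_target(s, b, "control", eps = 1e-9,
                             censor_at = 100)$censored)
  expect_error(time_to_target(numeric(), 5, "control"), "empty")

  # brute-force scan agreement on random series
  set.seed(21)
  for (rep in 1:20) {
    s <- cumsum(runif(60, -1, 2)) + 5
    bmk <- runif(1, 2, 12)
    ctrl <- time_to_target(s, bmk, "control")
    hit <- NA
    for (i in seq_along(s)) if (s[i] >= 0.99 * bmk) { hit <- i; break }
    expect_equal(ctrl$day, if (is.na(hit)) length(s) else hit)
    expect_equal(ctrl$censored, is.na(hit))
    cs <- time_to_target(s, bmk, "case")
    hit2 <- NA
    for (i in seq_along(s)) if (s[i] > bmk) { hit2 <- i; break }
    if (!is.na(hit2)) expect_equal(cs$day, max(hit2 - 1, 1))
  }
})

test_that("fractional crossings interpolate linearly between trough days", {
  s <- c(0, 1, 2, 3, 4)
  expect_equal(tamoxtrial:::fractional_crossing(s, 2.5), 3.5)
  expect_equal(tamoxtrial:::fractional_crossing(s, 0), 1)
  expect_true(is.na(tamoxtrial:::fractional_crossing(s, 9)))
  expect_equal(tamoxtrial:::fractional_crossing(s, 4, strict = FALSE), 5)
})

test_that("benchmark statistics behave and reproduce bit-exactly", {
  ps <- fixture_params()
  cal <- fixture_calendar()
  b1 <- compute_benchmark(seed = 5, params = ps, n = 120, calendar = cal,
                          window = 14)
  b2 <- compute_benchmark(seed = 5, params = ps, n = 120, calendar = cal,
                          window = 14)
  expect_identical(b1$value, b2$value)
  expect_true(b1$p5 < b1$p25 && b1$p25 < b1$value &&
                b1$value < b1$p75 && b1$p75 < b1$p95)
  expect_equal(b1$n, 120)
  # zero variability collapses all bands onto the median
  ps0 <- fixture_params(cv_clearance = 0, cv_volume = 0)
  b0 <- compute_benchmark(seed = 5, params = ps0, n = 10, calendar = cal)
  expect_equal(b0$p5, b0$value)
  expect_equal(b0$p95, b0$value)
})

test_that("a small full trial preserves the qualitative holiday structure", {
  # structural invariants hold under the shipped calibrated geometry (the
  # loading combination dominates the controls); small cohorts suffice
  ps <- default_parameters()
  cfg <- trial_config(seed = 11, n_per_arm = 40, params = ps)
  res <- run_virtual_trial(cfg)
  t2 <- res$table2
  expect_equal(nrow(t2), 20)
  expect_equal(sum(t2$group == "A"), 4)

  # identical seeds reproduce identically
  res2 <- run_virtual_trial(cfg)
  expect_identical(res$table2, res2$table2)

  # holiday washout: longer holidays leave lower endoxifen troughs
  for (ph in c("EM", "IM")) {
    tr <- t2[t2$group == "B" & t2$phenotype == ph & t2$role == "control", ]
    tr <- tr[order(tr$holiday_weeks), ]
    expect_true(all(diff(tr$holiday_end_trough_ugL) < 0))
  }

  # recovery time is non-decreasing in holiday length (uncensored cells)
  for (ph in c("EM", "IM")) for (role in c("case", "control")) {
    tr <- t2[t2$group == "B" & t2$phenotype == ph & t2$role == role, ]
    tr <- tr[order(tr$holiday_weeks), ]
    ok <- !tr$censored
    expect_true(all(diff(tr$time_to_target_day[ok]) >= 0))
  }

  # cases recover no later than their matched controls
  for (ph in c("EM", "IM")) for (w in c(2, 4, 8, 12)) {
    case <- t2[t2$phenotype == ph & t2$holiday_weeks == w & t2$role == "case", ]
    ctrl <- t2[t2$phenotype == ph & t2$holiday_weeks == w & t2$role == "control", ]
    expect_lte(case$time_to_target_day, ctrl$time_to_target_day)
  }

  # arm filtering and unknown ids
  cfg2 <- trial_config(seed = 11, n_per_arm = 10, params = ps,
                       arms = c("A-EM-control", "B-IM-case-2wk"),
                       calendar = fixture_calendar())
  expect_equal(nrow(run_virtual_trial(cfg2)$table2), 2)
  expect_error(run_virtual_trial(
    trial_config(seed = 1, n_per_arm = 5, params = ps, arms = "Z-arm",
                 calendar = fixture_calendar())), "unknown arm")
})
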