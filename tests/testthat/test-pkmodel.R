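test_that("rate matrix encodes the cascade topology and genotype scaling", {
  p <- fixture_network()
  A1 <- build_rate_matrix(p, cyp2d6_activity("EM", 1))
  A2 <- build_rate_matrix(p, cyp2d6_activity("IM", 0.5))
  A0 <- build_rate_matrix(p, cyp2d6_activity("PM", 0))

  # PM limit: both CYP2D6-mediated transfers vanish; END central receives
  # input only from 4OH->END and the END depot
  expect_identical(A0["4OH", "TAM"], 0)
  expect_identical(A0["END", "NDM"], 0)
  expect_gt(A0["END", "4OH"], 0)
  expect_gt(A0["END", "depot_END"], 0)

  # linear scaling: theta = 1 vs theta = 2 doubles exactly the CYP2D6 edges
  A4 <- build_rate_matrix(p, cyp2d6_activity("IM", 2))
  expect_equal(A4["4OH", "TAM"], 2 * A1["4OH", "TAM"])
  expect_equal(A4["END", "NDM"], 2 * A1["END", "NDM"])
  expect_equal(A4["NDM", "TAM"], A1["NDM", "TAM"]) # CYP3A4 untouched
  expect_equal(A4["END", "4OH"], A1["END", "4OH"])

  # off-diagonals non-negative, diagonals negative, column sums <= 0 with
  # strict deficit exactly where mass leaves the system
  for (A in list(A1, A2, A0)) {
    offd <- A; diag(offd) <- 0
    expect_true(all(offd >= 0))
    expect_true(all(diag(A) < 0))
    cs <- colSums(A)
    expect_true(all(cs <= 1e-12))
  }
  # with F = 1 the depot columns conserve mass; central columns eliminate
  expect_equal(sum(A1[, "depot_TAM"]), 0)
  expect_true(all(colSums(A1)[3:6] < 0))
})

test_that("rate matrix matches the hand-expanded ODE right-hand side", {
  # independent symbolic expansion of the six balance equations
  p <- fixture_network()
  th <- 0.7
  A <- build_rate_matrix(p, cyp2d6_activity("IM", th))
  set.seed(11)
  for (rep in 1:5) {
    x <- runif(6, 0.1, 10)
    rhs <- c(
      -p$ka_TAM * x[1],
      -p$ka_END * x[2],
      p$F_TAM * p$ka_TAM * x[1] -
        (p$CLf_TAM_NDM + th * p$CLf_TAM_4OH + p$CLe_TAM) / p$V_TAM * x[3],
      p$CLf_TAM_NDM / p$V_TAM * x[3] -
        (th * p$CLf_NDM_END + p$CLe_NDM) / p$V_NDM * x[4],
      th * p$CLf_TAM_4OH / p$V_TAM * x[3] -
        (p$CLf_4OH_END + p$CLe_4OH) / p$V_4OH * x[5],
      th * p$CLf_NDM_END / p$V_NDM * x[4] + p$CLf_4OH_END / p$V_4OH * x[5] +
        p$F_END * p$ka_END * x[2] - p$CLe_END / p$V_END * x[6]
    )
    expect_equal(unname(drop(A %*% x)), rhs, tolerance = 1e-12)
    # with F = 1 total mass leaves only through the elimination clearances
    clv <- c(p$CLe_TAM / p$V_TAM, p$CLe_NDM / p$V_NDM,
             p$CLe_4OH / p$V_4OH, p$CLe_END / p$V_END)
    A_full <- build_rate_matrix(fixture_network(F_END = 1),
                                cyp2d6_activity("IM", th))
    expect_equal(sum(A_full %*% x), -sum(clv * x[3:6]), tolerance = 1e-12)
  }
})

test_that("parameter and event validation rejects bad input", {
  expect_error(fixture_network(V_TAM = 0), "non-positive")
  expect_error(fixture_network(CLe_END = -1), "non-positive")
  expect_error(fixture_network(CLf_NDM_END = -2), "non-negative")
  expect_error(cyp2d6_activity("IM", -0.1), "non-negative")
  expect_error(cyp2d6_activity("EM", 0.5), "exactly 1")
  expect_error(dose_events(c(2, 1), c("TAM", "TAM"), c(5, 5)), "sorted")
  expect_error(dose_events(0, "XYZ", 5), "unknown compound")
  expect_error(dose_events(0, "TAM", -5), "strictly positive")
  p <- fixture_network()
  ev <- daily_tam_events(1:5)
  expect_error(pk_simulate(p, "EM", ev, horizon = 2), "horizon")
  expect_error(pk_simulate(p, "EM", ev, horizon = 10, sample_times = c(-1, 2)),
               "sample_times")
})

test_that("empty event stream yields identically zero concentrations", {
  ts <- pk_simulate(fixture_network(), "EM", dose_events(), horizon = 10)
  expect_true(all(ts$conc == 0))
  ts2 <- pk_simulate_ode(fixture_network(), "EM", dose_events(), horizon = 10)
  expect_true(all(ts2$conc == 0))
})

test_that("decoupled tamoxifen follows the closed-form oral Bateman curve", {
  p <- fixture_network(CLf_TAM_NDM = 0, CLf_TAM_4OH = 0, CLf_NDM_END = 0,
                       CLf_4OH_END = 0)
  D <- 20; ka <- p$ka_TAM; ke <- p$CLe_TAM / p$V_TAM
  tt <- seq(0, 21, by = 0.25)
  ts <- pk_simulate(p, "EM", dose_events(0, "TAM", D), horizon = 21,
                    sample_times = tt)
  bateman <- p$F_TAM * D * ka / (p$V_TAM * (ka - ke)) *
    (exp(-ke * tt) - exp(-ka * tt)) * 1000
  expect_equal(ts$conc[, "TAM"], bateman, tolerance = 1e-10)
  expect_true(all(ts$conc[, c("NDM", "4OH", "END")] == 0))
})

test_that("linearity: dose proportionality and superposition hold exactly", {
  p <- fixture_network()
  tt <- seq(0, 10, by = 0.5)
  one <- pk_simulate(p, "EM", dose_events(0, "TAM", 20), 10, tt)
  five <- pk_simulate(p, "EM", dose_events(0, "TAM", 100), 10, tt)
  expect_equal(five$conc, 5 * one$conc, tolerance = 1e-12)

  shifted <- pk_simulate(p, "EM", dose_events(1, "TAM", 20), 10, tt)
  both <- pk_simulate(p, "EM",
                      dose_events(c(0, 1), c("TAM", "TAM"), c(20, 20)), 10, tt)
  expect_equal(both$conc, one$conc + shifted$conc, tolerance = 1e-12)

  # mixed-compound superposition
  tam <- pk_simulate(p, "IM", dose_events(0, "TAM", 20), 10, tt)
  end <- pk_simulate(p, "IM", dose_events(2, "END", 3), 10, tt)
  mix <- pk_simulate(p, "IM",
                     dose_events(c(0, 2), c("TAM", "END"), c(20, 3)), 10, tt)
  expect_equal(mix$conc, tam$conc + end$conc, tolerance = 1e-12)
})

test_that("matrix-exponential path agrees with the adaptive ODE oracle", {
  set.seed(7)
  for (rep in 1:4) {
    mult <- exp(runif(16, -0.4, 0.4))
    fields <- c("ka_TAM", "ka_END", "F_TAM", "F_END", "V_TAM", "V_NDM",
                "V_4OH", "V_END", "CLf_TAM_NDM", "CLf_TAM_4OH",
                "CLf_NDM_END", "CLf_4OH_END", "CLe_TAM", "CLe_NDM",
                "CLe_4OH", "CLe_END")
    base <- unlist(fixture_network()[fields])
    vals <- as.list(base * mult)
    vals$F_TAM <- min(vals$F_TAM, 1); vals$F_END <- min(vals$F_END, 1)
    p <- do.call(network_params, vals)
    th <- runif(1, 0, 1.5)
    n_ev <- sample(3:8, 1)
    ev_t <- sort(round(runif(n_ev, 0, 12), 2))
    ev <- dose_events(ev_t, sample(c("TAM", "END"), n_ev, replace = TRUE),
                      round(runif(n_ev, 1, 25), 1))
    tt <- seq(0, 15, by = 0.5)
    a <- pk_simulate(p, cyp2d6_activity("IM", th), ev, 15, tt)
    b <- pk_simulate_ode(p, cyp2d6_activity("IM", th), ev, 15, tt)
    rel <- abs(a$conc - b$conc) / pmax(abs(b$conc), max(abs(b$conc)) * 1e-9)
    expect_lt(max(rel), 1e-6)
  }

  # zero-activity limit: both CYP2D6 edges vanish, so tamoxifen dosing
  # produces no 4OH and no END at all; agreement with the oracle holds
  pm <- pk_simulate(fixture_network(), cyp2d6_activity("PM", 0),
                    daily_tam_events(1:10), 12)
  pm_ode <- pk_simulate_ode(fixture_network(), cyp2d6_activity("PM", 0),
                            daily_tam_events(1:10), 12)
  expect_equal(pm$conc, pm_ode$conc, tolerance = 1e-6)
  expect_true(all(pm$conc[, c("4OH", "END")] == 0))
  expect_true(all(pm$conc[pm$time >= 2, c("TAM", "NDM")] > 0))
  # residual activity routes endoxifen through both CYP2D6-gated branches
  lowpm <- pk_simulate(fixture_network(), cyp2d6_activity("PM", 0.05),
                       daily_tam_events(1:10), 12)
  expect_true(all(lowpm$conc[lowpm$time >= 2, "END"] > 0))
})

test_that("states stay non-negative and total amount decays after dosing ends", {
  p <- fixture_network()
  ev <- daily_tam_events(1:14)
  tt <- seq(0, 40, by = 0.5)
  ts <- pk_simulate(p, "EM", ev, 40, tt)
  expect_true(all(ts$conc >= 0))
  # the parent declines once dosing and absorption end; metabolites may keep
  # rising while the parent feeds them, but all wash out eventually
  post <- ts$time > 14 + 5 / p$ka_TAM
  expect_true(all(diff(ts$conc[post, "TAM"]) <= 1e-12))
  late <- ts$time >= 30
  for (cmp in colnames(ts$conc)) {
    expect_true(all(diff(ts$conc[late, cmp]) < 0))
  }
  # total central amount is non-increasing after the last dose settles
  vols <- unlist(fixture_network()[c("V_TAM", "V_NDM", "V_4OH", "V_END")])
  total <- as.vector(ts$conc %*% (vols / 1000))
  expect_true(all(diff(total[post]) <= 1e-12))
})

test_that("steady-state endoxifen troughs order strictly EM > IM > PM", {
  p <- fixture_network()
  ev <- daily_tam_events(1:120)
  trough <- function(ph, th) {
    ts <- pk_simulate(p, cyp2d6_activity(ph, th), ev, 120,
                      sample_times = 110:120)
    mean(ts$conc[, "END"])
  }
  em <- trough("EM", 1); im <- trough("IM", 0.5); pm <- trough("PM", 0.1)
  expect_gt(em, im)
  expect_gt(im, pm)
  expect_gt(pm, 0)
})

test_that("concentration series export is tidy", {
  ts <- pk_simulate(fixture_network(), "EM", daily_tam_events(1:3), 5)
  df <- conc_ts_to_df(ts, patient_id = 7L)
  expect_equal(nrow(df), 4 * length(ts$time))
  expect_named(df, c("time_day", "compound", "concentration_ug_per_L",
                     "patient_id"))
  expect_equal(unique(df$patient_id), 7L)
  expect_equal(df$concentration_ug_per_L[df$compound == "TAM"],
               unname(ts$conc[, "TAM"]))
})
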