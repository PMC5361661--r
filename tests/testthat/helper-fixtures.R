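# Small, fast fixtures used across the unit tests. These are NOT the shipped
# calibrated values; they are simple round numbers with the right orders of
# magnitude so analytic checks stay readable.

fixture_network <- function(...) {
  defaults <- list(
    ka_TAM = 5, ka_END = 6, F_TAM = 1, F_END = 0.9,
    V_TAM = 1000, V_NDM = 1200, V_4OH = 800, V_END = 400,
    CLf_TAM_NDM = 80, CLf_TAM_4OH = 6, CLf_NDM_END = 8,
    CLf_4OH_END = 700, CLe_TAM = 30, CLe_NDM = 40, CLe_4OH = 100,
    CLe_END = 140
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(network_params, defaults)
}

fixture_params <- function(cv_clearance = 0.3, cv_volume = 0.15, ...) {
  param_set(fixture_network(...),
            theta = c(EM = 1, IM = 0.5, PM = 0.1),
            cv_clearance = cv_clearance, cv_volume = cv_volume)
}

# A compressed trial calendar: 6-week run-in, 13-week intake. Keeps whole
# trial runs fast while preserving run-in >> holiday >> daily structure.
fixture_calendar <- function() {
  trial_calendar(run_in_days = 42L, intake_days = 91L, censor_day = 140L)
}

daily_tam_events <- function(days, amount = 20) {
  dose_events(time = days - 1, compound = rep("TAM", length(days)),
              amount = rep(amount, length(days)))
}

# Independent sort-based quantile oracle (type-7 convention, written out).
naive_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
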