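## Daily regimens used in the trial (mg once daily).
TX_REGIMENS <- list(
  "20 TAM"         = c(TAM = 20, END = 0),
  "20 TAM + 1 END" = c(TAM = 20, END = 1),
  "20 TAM + 3 END" = c(TAM = 20, END = 3)
)

#' Calendar conventions of the virtual trial
#'
#' Day 1 is the first dose day; doses are instantaneous daily boluses and
#' troughs are sampled immediately before the next scheduled dose (24 h
#' interval). The 6-month run-in is 168 days (24 weeks); dosing continues
#' until 12 months (364 days) of intake are completed, so a Group B arm with
#' an `w`-week holiday runs to day `364 + 7w`. Times to target in Group B
#' control arms are censored at calendar day 336 when never reached.
#'
#' @param run_in_days Length of the run-in phase in days.
#' @param intake_days Total days of drug intake per arm.
#' @param censor_day Calendar day at which unreached control times are
#'   censored.
#' @return A list of class `trial_calendar`.
#' @export
trial_calendar <- function(run_in_days = 168L, intake_days = 364L,
                           censor_day = 336L) {
  structure(list(run_in_days = as.integer(run_in_days),
                 intake_days = as.integer(intake_days),
                 censor_day = as.integer(censor_day)),
            class = "trial_calendar")
}

#' Specification of one trial arm
#'
#' Group A arms dose continuously for 12 months. Group B arms dose a run-in
#' regimen for 6 months, pause for a drug holiday of 2, 4, 8 or 12 weeks,
#' then resume with the post-holiday regimen until 12 months of intake are
#' completed. Case arms resume (or start) with the fixed-dose combination of
#' 20 mg tamoxifen + 3 mg endoxifen; control arms use the phenotype's
#' reference regimen (20 mg TAM for EMs, 20 mg TAM + 1 mg END for IMs).
#'
#' @param group `"A"` (continuous) or `"B"` (drug holiday).
#' @param phenotype `"EM"` or `"IM"`.
#' @param role `"case"` or `"control"`.
#' @param holiday_weeks 0 for Group A; 2, 4, 8 or 12 for Group B.
#' @return A list of class `arm_spec` with an `arm_id` like
#'   `"B-IM-case-8wk"` and run-in/post regimens in mg/day.
#' @export
arm_spec <- function(group = c("A", "B"), phenotype = c("EM", "IM"),
                     role = c("case", "control"), holiday_weeks = 0L) {
  group <- match.arg(group)
  phenotype <- match.arg(phenotype)
  role <- match.arg(role)
  holiday_weeks <- as.integer(holiday_weeks)
  if (group == "A" && holiday_weeks != 0L) {
    stop("Group A arms have no drug holiday")
  }
  if (group == "B" && !holiday_weeks %in% c(0L, 2L, 4L, 8L, 12L)) {
    # 0 weeks is the degenerate holiday (continuous dosing); the trial
    # itself only enumerates 2, 4, 8 and 12 weeks.
    stop("Group B holidays are 0 (degenerate), 2, 4, 8 or 12 weeks")
  }
  reference <- if (phenotype == "EM") "20 TAM" else "20 TAM + 1 END"
  combo <- "20 TAM + 3 END"
  if (group == "A") {
    run_in <- post <- if (role == "case") combo else reference
  } else {
    run_in <- reference
    post <- if (role == "case") combo else reference
  }
  arm_id <- if (group == "A") {
    sprintf("A-%s-%s", phenotype, role)
  } else {
    sprintf("B-%s-%s-%dwk", phenotype, role, holiday_weeks)
  }
  structure(list(arm_id = arm_id, group = group, phenotype = phenotype,
                 role = role, holiday_weeks = holiday_weeks,
                 run_in_regimen = run_in, post_regimen = post),
            class = "arm_spec")
}

#' Enumerate the 20 trial arms
#'
#' Four Group A arms (EM/IM x case/control) and sixteen Group B arms
#' (EM/IM x case/control x holidays of 2, 4, 8, 12 weeks), with stable ids.
#'
#' @return A list of 20 [arm_spec()] objects, Group A first.
#' @export
enumerate_arms <- function() {
  arms <- list()
  for (ph in c("EM", "IM")) for (role in c("case", "control")) {
    arms[[length(arms) + 1L]] <- arm_spec("A", ph, role)
  }
  for (ph in c("EM", "IM")) for (role in c("case", "control")) {
    for (w in c(2L, 4L, 8L, 12L)) {
      arms[[length(arms) + 1L]] <- arm_spec("B", ph, role, w)
    }
  }
  names(arms) <- vapply(arms, `[[`, "", "arm_id")
  arms
}

regimen_amounts <- function(regimen) {
  amt <- TX_REGIMENS[[regimen]]
  if (is.null(amt)) stop("unknown regimen: ", regimen)
  amt
}

regimen_events <- function(days, regimen) {
  amt <- regimen_amounts(regimen)
  compounds <- names(amt)[amt > 0]
  data.frame(
    time = rep(days - 1, each = length(compounds)),
    compound = rep(compounds, times = length(days)),
    amount = rep(amt[compounds], times = length(days))
  )
}

#' Build the dose-event stream of a trial arm
#'
#' Group A: daily events on days `1..intake_days`. Group B: run-in events on
#' days `1..run_in_days`, exactly `7 * holiday_weeks` dose-free days, then
#' post-holiday events from day `run_in_days + 7 * holiday_weeks + 1` through
#' day `intake_days + 7 * holiday_weeks`. A dose on day `d` is an
#' instantaneous bolus at time `d - 1`, so the trough of day `d` (sampled at
#' time `d - 1`, pre-dose) reflects all doses of days `1..d-1`.
#'
#' @param spec An [arm_spec()].
#' @param calendar A [trial_calendar()].
#' @return An object of class `protocol`: the [dose_events()] stream with
#'   attributes `arm_id`, `run_in_end_day`, `holiday_end_day`, `restart_day`,
#'   `horizon_day`.
#' @export
build_protocol <- function(spec, calendar = trial_calendar()) {
  stopifnot(inherits(spec, "arm_spec"))
  if (spec$group == "A") {
    horizon <- calendar$intake_days
    ev <- regimen_events(seq_len(horizon), spec$post_regimen)
    run_in_end <- 0L
    holiday_end <- 0L
    restart <- 1L
  } else {
    gap <- 7L * spec$holiday_weeks
    run_in_end <- calendar$run_in_days
    holiday_end <- run_in_end + gap
    restart <- holiday_end + 1L
    horizon <- calendar$intake_days + gap
    ev <- rbind(
      regimen_events(seq_len(run_in_end), spec$run_in_regimen),
      regimen_events(seq(restart, horizon), spec$post_regimen)
    )
  }
  ev <- ev[order(ev$time, ev$compound), , drop = FALSE]
  rownames(ev) <- NULL
  out <- dose_events(ev$time, ev$compound, ev$amount)
  attr(out, "arm_id") <- spec$arm_id
  attr(out, "run_in_end_day") <- run_in_end
  attr(out, "holiday_end_day") <- holiday_end
  attr(out, "restart_day") <- restart
  attr(out, "horizon_day") <- as.integer(horizon)
  class(out) <- c("protocol", class(out))
  out
}

#' Daily dose matrix of a protocol
#'
#' Collapses a protocol into a `6 x horizon` matrix of per-day bolus amounts
#' over the state vector (only the two depot rows can be non-zero); column
#' `d` is the dose administered on day `d` at time `d - 1`.
#'
#' @param protocol A [build_protocol()] result.
#' @return A `6 x horizon_day` numeric matrix.
#' @export
protocol_dose_matrix <- function(protocol) {
  stopifnot(inherits(protocol, "protocol"))
  horizon <- attr(protocol, "horizon_day")
  doses <- matrix(0, 6L, horizon, dimnames = list(TX_STATES, NULL))
  day <- as.integer(protocol$time) + 1L
  row <- ifelse(protocol$compound == "TAM", 1L, 2L)
  for (k in seq_len(nrow(protocol))) {
    doses[row[k], day[k]] <- doses[row[k], day[k]] + protocol$amount[k]
  }
  doses
}
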