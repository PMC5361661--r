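#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Central compounds of the metabolic cascade, in state order.
TX_COMPOUNDS <- c("TAM", "NDM", "4OH", "END")

## Full state vector: two oral depots followed by the four central amounts.
TX_STATES <- c("depot_TAM", "depot_END", "TAM", "NDM", "4OH", "END")

## Clearance and volume field names of a parameter set; used for validation
## and for population sampling (clearances share one CV, volumes another).
TX_CLEARANCES <- c("CLf_TAM_NDM", "CLf_TAM_4OH", "CLf_NDM_END", "CLf_4OH_END",
                   "CLe_TAM", "CLe_NDM", "CLe_4OH", "CLe_END")
TX_VOLUMES <- c("V_TAM", "V_NDM", "V_4OH", "V_END")

#' Kinetic parameters of the tamoxifen metabolic cascade
#'
#' Builds and validates the parameter set of the reduced linear kinetic model:
#' one central compartment per compound (tamoxifen TAM, N-desmethyltamoxifen
#' NDM, 4-hydroxytamoxifen 4OH, endoxifen END) plus first-order oral depots
#' for the two dosed compounds (TAM and END). Formation pathways follow the
#' standard tamoxifen cascade: TAM->NDM and 4OH->END are CYP3A4-mediated,
#' TAM->4OH and NDM->END are CYP2D6-mediated and are scaled by the phenotype
#' activity multiplier (see [cyp2d6_activity()]).
#'
#' @param ka_TAM,ka_END First-order absorption rate constants (1/day).
#' @param F_TAM,F_END Oral bioavailability fractions in (0, 1].
#' @param V_TAM,V_NDM,V_4OH,V_END Apparent volumes of distribution (L).
#' @param CLf_TAM_NDM Formation clearance TAM->NDM, CYP3A4 (L/day).
#' @param CLf_TAM_4OH Formation clearance TAM->4OH, CYP2D6-scaled (L/day).
#' @param CLf_NDM_END Formation clearance NDM->END, CYP2D6-scaled (L/day).
#' @param CLf_4OH_END Formation clearance 4OH->END, CYP3A4 (L/day).
#' @param CLe_TAM,CLe_NDM,CLe_4OH,CLe_END Non-pathway elimination clearances
#'   (L/day).
#' @return A validated list of class `network_params`.
#' @export
network_params <- function(ka_TAM, ka_END, F_TAM, F_END,
                           V_TAM, V_NDM, V_4OH, V_END,
                           CLf_TAM_NDM, CLf_TAM_4OH, CLf_NDM_END, CLf_4OH_END,
                           CLe_TAM, CLe_NDM, CLe_4OH, CLe_END) {
  p <- as.list(environment())
  validate_network_params(p)
  structure(p, class = "network_params")
}

validate_network_params <- function(p) {
  need <- c("ka_TAM", "ka_END", "F_TAM", "F_END", TX_VOLUMES, TX_CLEARANCES)
  missing <- setdiff(need, names(p))
  if (length(missing) > 0L) {
    stop("missing network parameters: ", paste(missing, collapse = ", "))
  }
  vals <- unlist(p[need])
  if (!all(is.finite(vals))) stop("network parameters must be finite numbers")
  strict <- c("ka_TAM", "ka_END", "F_TAM", "F_END", TX_VOLUMES,
              "CLe_TAM", "CLe_NDM", "CLe_4OH", "CLe_END")
  if (any(unlist(p[strict]) <= 0)) {
    stop("non-positive network parameter: ",
         paste(strict[unlist(p[strict]) <= 0], collapse = ", "))
  }
  # Formation clearances may be zero (decoupled limits, CYP2D6 scaling);
  # every species still eliminates through its non-pathway clearance.
  form <- c("CLf_TAM_NDM", "CLf_TAM_4OH", "CLf_NDM_END", "CLf_4OH_END")
  if (any(unlist(p[form]) < 0)) {
    stop("formation clearances must be non-negative")
  }
  if (p$F_TAM > 1 || p$F_END > 1) stop("bioavailability fractions must be <= 1")
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("Tamoxifen cascade kinetic parameters (reduced linear model)\n")
  cat(sprintf("  absorption : ka_TAM %.3g/d, ka_END %.3g/d, F_TAM %.3g, F_END %.3g\n",
              x$ka_TAM, x$ka_END, x$F_TAM, x$F_END))
  cat(sprintf("  volumes [L]: TAM %.4g, NDM %.4g, 4OH %.4g, END %.4g\n",
              x$V_TAM, x$V_NDM, x$V_4OH, x$V_END))
  cat(sprintf("  formation [L/d]: TAM->NDM %.4g (3A4), TAM->4OH %.4g (2D6),\n",
              x$CLf_TAM_NDM, x$CLf_TAM_4OH))
  cat(sprintf("                   NDM->END %.4g (2D6), 4OH->END %.4g (3A4)\n",
              x$CLf_NDM_END, x$CLf_4OH_END))
  cat(sprintf("  elimination [L/d]: TAM %.4g, NDM %.4g, 4OH %.4g, END %.4g\n",
              x$CLe_TAM, x$CLe_NDM, x$CLe_4OH, x$CLe_END))
  invisible(x)
}

#' CYP2D6 phenotype activity
#'
#' The three metabolizer classes are represented by a single activity
#' multiplier `theta` applied to the CYP2D6-mediated formation clearances.
#' Extensive metabolizers (EM) are the reference with `theta = 1` exactly;
#' intermediate (IM) and poor (PM) metabolizers have `1 > theta(IM) >
#' theta(PM) >= 0`.
#'
#' @param phenotype One of `"EM"`, `"IM"`, `"PM"`.
#' @param theta Activity multiplier; defaults to the shipped calibrated value
#'   for the phenotype (see [default_parameters()]).
#' @return An object of class `cyp2d6_activity`.
#' @export
cyp2d6_activity <- function(phenotype = c("EM", "IM", "PM"), theta = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(theta)) theta <- default_parameters()$theta[[phenotype]]
  if (!is.finite(theta) || theta < 0) stop("theta must be a non-negative number")
  if (phenotype == "EM" && theta != 1) stop("theta(EM) must be exactly 1")
  structure(list(phenotype = phenotype, theta = theta),
            class = "cyp2d6_activity")
}

as_activity <- function(activity) {
  if (inherits(activity, "cyp2d6_activity")) return(activity)
  if (is.character(activity) && length(activity) == 1L) {
    return(cyp2d6_activity(activity))
  }
  stop("'activity' must be a cyp2d6_activity object or a phenotype label")
}

#' Rate matrix of the dosed metabolic cascade
#'
#' Assembles the 6x6 first-order rate matrix over the state vector
#' `(depot_TAM, depot_END, TAM, NDM, 4OH, END)` (amounts in mg). Depot
#' states drain with `ka`; the bioavailable fraction `F` enters the central
#' compartment and `1 - F` is lost. Formation clearances move mass between
#' central compartments; CYP2D6-mediated entries are scaled by the activity
#' multiplier. Diagonal entries are the negative total outflow rates, so
#' column sums are `<= 0` with strict deficit in columns that eliminate mass.
#'
#' @param params A [network_params()] set.
#' @param activity A [cyp2d6_activity()] object (or phenotype label).
#' @return A 6x6 numeric matrix (1/day) with dimnames `TX_STATES`.
#' @export
build_rate_matrix <- function(params, activity) {
  validate_network_params(params)
  activity <- as_activity(activity)
  th <- activity$theta
  p <- params
  A <- matrix(0, 6L, 6L, dimnames = list(TX_STATES, TX_STATES))
  A[1L, 1L] <- -p$ka_TAM
  A[3L, 1L] <- p$F_TAM * p$ka_TAM
  A[2L, 2L] <- -p$ka_END
  A[6L, 2L] <- p$F_END * p$ka_END
  k_out_TAM <- (p$CLf_TAM_NDM + th * p$CLf_TAM_4OH + p$CLe_TAM) / p$V_TAM
  A[3L, 3L] <- -k_out_TAM
  A[4L, 3L] <- p$CLf_TAM_NDM / p$V_TAM
  A[5L, 3L] <- th * p$CLf_TAM_4OH / p$V_TAM
  A[4L, 4L] <- -(th * p$CLf_NDM_END + p$CLe_NDM) / p$V_NDM
  A[6L, 4L] <- th * p$CLf_NDM_END / p$V_NDM
  A[5L, 5L] <- -(p$CLf_4OH_END + p$CLe_4OH) / p$V_4OH
  A[6L, 5L] <- p$CLf_4OH_END / p$V_4OH
  A[6L, 6L] <- -p$CLe_END / p$V_END
  A
}

#' Dose event stream
#'
#' Validates a stream of instantaneous oral bolus events. Doses enter the
#' oral depot of the corresponding compound at the scheduled time.
#'
#' @param time Event times in days (dose on calendar day `d` occurs at time
#'   `d - 1`, so troughs sampled at integer times are pre-dose).
#' @param compound `"TAM"` or `"END"` per event.
#' @param amount Dose amounts in mg, strictly positive.
#' @return A `data.frame` of class `dose_events`, sorted by time.
#' @export
dose_events <- function(time = numeric(), compound = character(),
                        amount = numeric()) {
  if (length(time) != length(compound) || length(time) != length(amount)) {
    stop("time, compound and amount must have equal length")
  }
  if (length(time) > 0L) {
    if (any(!compound %in% c("TAM", "END"))) {
      stop("dose of unknown compound: only TAM and END can be dosed orally")
    }
    if (any(!is.finite(time)) || any(time < 0)) stop("event times must be >= 0")
    if (any(!is.finite(amount)) || any(amount <= 0)) {
      stop("dose amounts must be strictly positive")
    }
    if (is.unsorted(time)) stop("dose events must be sorted by time")
  }
  structure(data.frame(time = as.numeric(time),
                       compound = as.character(compound),
                       amount = as.numeric(amount)),
            class = c("dose_events", "data.frame"))
}

## Collapse an event stream to per-time 6-state bolus vectors.
event_boluses <- function(events) {
  if (nrow(events) == 0L) {
    return(list(times = numeric(), boluses = matrix(0, 6L, 0L)))
  }
  times <- sort(unique(events$time))
  boluses <- matrix(0, 6L, length(times), dimnames = list(TX_STATES, NULL))
  idx <- match(events$time, times)
  row <- ifelse(events$compound == "TAM", 1L, 2L)
  for (k in seq_len(nrow(events))) {
    boluses[row[k], idx[k]] <- boluses[row[k], idx[k]] + events$amount[k]
  }
  list(times = times, boluses = boluses)
}

## Matrix-exponential propagator with caching over repeated interval lengths
## (daily dosing reuses a single exponential).
make_propagator <- function(A) {
  cache <- new.env(parent = emptyenv())
  function(dt) {
    key <- sprintf("%.12g", dt)
    P <- cache[[key]]
    if (is.null(P)) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
      cache[[key]] <- P
    }
    P
  }
}

#' Simulate the cascade under a dose-event stream
#'
#' Exact simulation of the linear kinetic system: between dose events the
#' state evolves by the matrix-exponential propagator; at event times the
#' dose amount is added instantaneously to the oral depot. Samples taken at
#' an event time are pre-dose. The result is deterministic given its inputs.
#'
#' @param params A [network_params()] set.
#' @param activity A [cyp2d6_activity()] object or phenotype label.
#' @param events A [dose_events()] stream (or data.frame coercible to one).
#' @param horizon Simulation end time (days), `>=` the last event time.
#' @param sample_times Times (days) at which to report concentrations; must
#'   lie within `[0, horizon]`.
#' @param state0 Optional initial 6-state amount vector (mg), default zero.
#' @return An object of class `conc_ts`: list with `time` (days) and `conc`,
#'   a `length(time) x 4` matrix of plasma concentrations (ug/L) for
#'   TAM, NDM, 4OH, END (`central amount * 1000 / V`).
#' @export
pk_simulate <- function(params, activity, events, horizon,
                        sample_times = seq(0, horizon, by = 1),
                        state0 = NULL) {
  events <- as_dose_events(events)
  check_sim_window(events, horizon, sample_times)
  A <- build_rate_matrix(params, activity)
  prop <- make_propagator(A)
  ev <- event_boluses(events)
  s <- if (is.null(state0)) numeric(6L) else check_state0(state0)

  n_out <- length(sample_times)
  out <- matrix(NA_real_, n_out, 4L, dimnames = list(NULL, TX_COMPOUNDS))
  ord <- order(sample_times)
  st <- sample_times[ord]

  # Merged timeline: at equal times, samples are taken before the bolus.
  t_cur <- 0
  i_ev <- 1L
  i_s <- 1L
  record <- function(i, s) t(s[3:6]) # amounts; converted to conc below
  while (i_s <= n_out || i_ev <= length(ev$times)) {
    t_next_s <- if (i_s <= n_out) st[i_s] else Inf
    t_next_e <- if (i_ev <= length(ev$times)) ev$times[i_ev] else Inf
    t_next <- min(t_next_s, t_next_e)
    if (t_next > t_cur) {
      s <- drop(prop(t_next - t_cur) %*% s)
      t_cur <- t_next
    }
    while (i_s <= n_out && st[i_s] == t_cur) { # pre-dose sampling
      out[ord[i_s], ] <- s[3:6]
      i_s <- i_s + 1L
    }
    if (i_ev <= length(ev$times) && ev$times[i_ev] == t_cur) {
      s <- s + ev$boluses[, i_ev]
      i_ev <- i_ev + 1L
    }
  }
  vols <- unlist(params[TX_VOLUMES])
  conc <- sweep(out, 2L, 1000 / vols, `*`)
  new_conc_ts(sample_times, conc)
}

as_dose_events <- function(events) {
  if (inherits(events, "dose_events")) return(events)
  if (is.data.frame(events)) {
    return(dose_events(events$time, events$compound, events$amount))
  }
  stop("'events' must be a dose_events object or a compatible data.frame")
}

check_sim_window <- function(events, horizon, sample_times) {
  if (!is.finite(horizon) || horizon < 0) stop("horizon must be >= 0")
  if (nrow(events) > 0L && horizon < max(events$time)) {
    stop("horizon must be >= the last event time")
  }
  if (length(sample_times) > 0L &&
      (min(sample_times) < 0 || max(sample_times) > horizon)) {
    stop("sample_times must lie within [0, horizon]")
  }
}

check_state0 <- function(state0) {
  if (length(state0) != 6L || any(!is.finite(state0)) || any(state0 < 0)) {
    stop("state0 must be 6 non-negative amounts")
  }
  as.numeric(state0)
}

new_conc_ts <- function(time, conc) {
  stopifnot(length(time) == nrow(conc))
  structure(list(time = as.numeric(time), conc = conc), class = "conc_ts")
}

#' @export
print.conc_ts <- function(x, ...) {
  cat(sprintf("Concentration time series: %d samples over %.4g-%.4g days\n",
              length(x$time), min(x$time), max(x$time)))
  cat("  final [ug/L]: ",
      paste(sprintf("%s %.4g", TX_COMPOUNDS, x$conc[nrow(x$conc), ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy export of a concentration time series
#'
#' @param x A `conc_ts` object.
#' @param patient_id Identifier recycled into the `patient_id` column.
#' @return A tibble with columns `time_day`, `compound`,
#'   `concentration_ug_per_L`, `patient_id`.
#' @export
conc_ts_to_df <- function(x, patient_id = 1L) {
  stopifnot(inherits(x, "conc_ts"))
  tibble::tibble(
    time_day = rep(x$time, times = 4L),
    compound = rep(TX_COMPOUNDS, each = length(x$time)),
    concentration_ug_per_L = as.vector(x$conc),
    patient_id = patient_id
  )
}

#' Independent ODE oracle for the cascade simulation
#'
#' Recomputes the contract of [pk_simulate()] by adaptive numeric integration
#' (`deSolve::lsoda`) of the hand-written right-hand side, restarting the
#' integrator at each bolus. This path shares no propagation code with
#' [pk_simulate()] and serves as its independent verification.
#'
#' @inheritParams pk_simulate
#' @param rtol,atol Integrator tolerances.
#' @return A `conc_ts` object.
#' @export
pk_simulate_ode <- function(params, activity, events, horizon,
                            sample_times = seq(0, horizon, by = 1),
                            state0 = NULL, rtol = 1e-10, atol = 1e-12) {
  events <- as_dose_events(events)
  check_sim_window(events, horizon, sample_times)
  activity <- as_activity(activity)
  th <- activity$theta
  p <- params
  rhs <- function(t, y, parms) {
    depot_T <- y[1L]; depot_E <- y[2L]
    tam <- y[3L]; ndm <- y[4L]; oh <- y[5L]; end <- y[6L]
    list(c(
      -p$ka_TAM * depot_T,
      -p$ka_END * depot_E,
      p$F_TAM * p$ka_TAM * depot_T -
        (p$CLf_TAM_NDM + th * p$CLf_TAM_4OH + p$CLe_TAM) / p$V_TAM * tam,
      p$CLf_TAM_NDM / p$V_TAM * tam -
        (th * p$CLf_NDM_END + p$CLe_NDM) / p$V_NDM * ndm,
      th * p$CLf_TAM_4OH / p$V_TAM * tam -
        (p$CLf_4OH_END + p$CLe_4OH) / p$V_4OH * oh,
      th * p$CLf_NDM_END / p$V_NDM * ndm + p$CLf_4OH_END / p$V_4OH * oh +
        p$F_END * p$ka_END * depot_E - p$CLe_END / p$V_END * end
    ))
  }
  y <- if (is.null(state0)) numeric(6L) else check_state0(state0)
  names(y) <- TX_STATES
  ev <- event_boluses(events)
  times <- sort(unique(c(0, sample_times, ev$times, horizon)))
  evdat <- NULL
  if (length(ev$times) > 0L) {
    nz <- which(ev$boluses != 0, arr.ind = TRUE)
    evdat <- data.frame(var = TX_STATES[nz[, 1L]],
                        time = ev$times[nz[, 2L]],
                        value = ev$boluses[cbind(nz[, 1L], nz[, 2L])],
                        method = "add")
    evdat <- evdat[order(evdat$time), ]
  }
  sol <- deSolve::lsoda(y, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                        events = if (is.null(evdat)) NULL else list(data = evdat),
                        maxsteps = 50000)
  if (attr(sol, "istate")[1L] < 0) {
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "))
  }
  idx <- match(round(sample_times, 10), round(sol[, "time"], 10))
  amounts <- sol[idx, 4:7, drop = FALSE]
  vols <- unlist(params[TX_VOLUMES])
  conc <- sweep(amounts, 2L, 1000 / vols, `*`)
  colnames(conc) <- TX_COMPOUNDS
  new_conc_ts(sample_times, conc)
}
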