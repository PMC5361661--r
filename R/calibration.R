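## ---- calibrated parameter sets -------------------------------------------

PARAM_SET_VERSION <- "1.0"

#' The shipped calibrated parameter set
#'
#' Typical kinetic parameters, CYP2D6 activity multipliers, population CVs
#' and the achievement tolerance of the control crossing rule, calibrated so
#' that the virtual trial reproduces the published time-to-steady-state day
#' counts and trough anchors (see the methods vignette for the calibration
#' design). The kinetic values themselves are not published observables;
#' they are identified only through the trial-level anchors.
#'
#' @return A list of class `param_set` with elements `network`
#'   ([network_params()]), `theta` (named EM/IM/PM multipliers), `cv`
#'   (`clearance`, `volume`), `eps_achieve`, `version` and `provenance`.
#' @export
default_parameters <- function() {
  param_set(
    network_params(
      ka_TAM =       5, ka_END = 7.65333, F_TAM =       1, F_END = 0.939155,
      V_TAM =    1000, V_NDM =    1400, V_4OH =     800, V_END = 188.027,
      CLf_TAM_NDM = 4.74502, CLf_TAM_4OH = 12.5262, CLf_NDM_END = 75.1801,
      CLf_4OH_END = 814.916, CLe_TAM = 70.0647, CLe_NDM = 20.0104, CLe_4OH = 159.312,
      CLe_END = 146.439
    ),
    theta = c(EM = 1, IM = 0.655579, PM = 0.118302),
    cv_clearance =     0.8, cv_volume =     0.2,
    eps_achieve = 0.01,
    provenance = list(
      method = "staged multistart Nelder-Mead against the printed trial anchors; final stage fitted at full population level (n = 1000, common random numbers)",
      seed = 20170314L, n_final = 1000L)
  )
}

#' Assemble a parameter set from components
#'
#' @param network A [network_params()] set.
#' @param theta Named activity multipliers; `theta["EM"]` must be 1 and
#'   `theta(EM) > theta(IM) > theta(PM) >= 0`.
#' @param cv_clearance,cv_volume Population coefficients of variation.
#' @param eps_achieve Achievement tolerance of the control crossing rule.
#' @param provenance Free-form provenance list.
#' @return A `param_set`.
#' @export
param_set <- function(network, theta = c(EM = 1, IM = 0.55, PM = 0.1),
                      cv_clearance = 0.35, cv_volume = 0.20,
                      eps_achieve = 0.01, provenance = list()) {
  validate_network_params(network)
  if (theta[["EM"]] != 1) stop("theta(EM) must be exactly 1")
  if (!(theta[["EM"]] > theta[["IM"]] && theta[["IM"]] > theta[["PM"]] &&
        theta[["PM"]] >= 0)) {
    stop("activity ordering must satisfy theta(EM) > theta(IM) > theta(PM) >= 0")
  }
  if (cv_clearance < 0 || cv_volume < 0) stop("CVs must be >= 0")
  structure(list(network = network, theta = theta,
                 cv = list(clearance = cv_clearance, volume = cv_volume),
                 eps_achieve = eps_achieve, version = PARAM_SET_VERSION,
                 provenance = provenance),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("Calibrated parameter set (version %s)\n", x$version))
  cat(sprintf("  theta: EM %.3g, IM %.3g, PM %.3g; CVs: clearance %.2f, volume %.2f\n",
              x$theta[["EM"]], x$theta[["IM"]], x$theta[["PM"]],
              x$cv$clearance, x$cv$volume))
  print(x$network)
  invisible(x)
}

#' Write / read a parameter set as flat YAML
#'
#' The file is a flat key-value map carrying a `version` tag; reading
#' validates the schema (every kinetic field present and numeric).
#'
#' @param params A `param_set`.
#' @param path File path.
#' @return `write_param_set` returns `path` invisibly; `read_param_set`
#'   returns a `param_set`.
#' @export
write_param_set <- function(params, path) {
  stopifnot(inherits(params, "param_set"))
  flat <- c(list(version = params$version),
            unclass(params$network),
            list(theta_EM = params$theta[["EM"]],
                 theta_IM = params$theta[["IM"]],
                 theta_PM = params$theta[["PM"]],
                 cv_clearance = params$cv$clearance,
                 cv_volume = params$cv$volume,
                 eps_achieve = params$eps_achieve))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_param_set
#' @export
read_param_set <- function(path) {
  flat <- yaml::read_yaml(path)
  need <- c("version", "theta_IM", "theta_PM", "cv_clearance", "cv_volume",
            "eps_achieve", "ka_TAM", "ka_END", "F_TAM", "F_END",
            TX_VOLUMES, TX_CLEARANCES)
  missing <- setdiff(need, names(flat))
  if (length(missing) > 0L) {
    stop("parameter file is missing keys: ", paste(missing, collapse = ", "))
  }
  num <- flat[setdiff(need, "version")]
  if (!all(vapply(num, is.numeric, logical(1L)))) {
    stop("parameter file contains non-numeric values")
  }
  net <- do.call(network_params,
                 flat[c("ka_TAM", "ka_END", "F_TAM", "F_END",
                        TX_VOLUMES, TX_CLEARANCES)])
  param_set(net,
            theta = c(EM = 1, IM = flat$theta_IM, PM = flat$theta_PM),
            cv_clearance = flat$cv_clearance, cv_volume = flat$cv_volume,
            eps_achieve = flat$eps_achieve,
            provenance = list(file = path, version = flat$version))
}

## ---- trial observables ----------------------------------------------------

#' Trial-level observables of a parameter set
#'
#' Runs the virtual trial (benchmark + 20 arms + a PM equalization cohort)
#' and extracts the statistics the calibration anchors constrain. Time
#' observables are continuous threshold-crossing times of the median
#' endoxifen trough series (linear interpolation between trough days), on
#' the trial's day-counting convention: a control anchor of day `d`
#' corresponds to a fractional crossing near `d - 0.5`, a case anchor of day
#' `d` (the day before strict exceedance) to `d + 0.5`. Concentrations are
#' ug/L. With `n = 1` the population CVs are zeroed and the observables are
#' the deterministic typical-patient values (computed by a fast
#' single-patient path).
#'
#' @param params A `param_set`.
#' @param n Patients per cohort.
#' @param seed Population seed (ignored in the deterministic mode).
#' @param calendar A [trial_calendar()].
#' @return Named numeric vector: `tt_*` fractional days, `ct_*` trough
#'   anchors, `benchmark_median`, `benchmark_p25`, and steady-state ratios
#'   `ratio_IM_control_ss`, `ratio_PM_combo_ss`. Censored crossings are
#'   reported as the observation limit plus 100 days.
#' @export
compute_trial_observables <- function(params, n = 200L, seed = 1L,
                                      calendar = trial_calendar()) {
  if (n == 1L) return(compute_typical_observables(params, calendar))
  cfg <- trial_config(seed = seed, n_per_arm = n, params = params,
                      calendar = calendar)
  res <- run_virtual_trial(cfg)
  B <- res$benchmark$value
  out <- observables_from_series(res$series, B, params$eps_achieve)
  out["benchmark_median"] <- B
  out["benchmark_p25"] <- res$benchmark$p25

  pm_spec <- population_spec(n, "PM", params$cv$clearance, params$cv$volume,
                             seed = seed)
  pm_pop <- sample_population(pm_spec, params$network,
                              theta = params$theta[["PM"]])
  pm_tr <- run_arm(build_protocol(arm_spec("A", "EM", "case"), calendar),
                   pm_pop)
  pm_med <- arm_median_series(pm_tr)
  out["ratio_PM_combo_ss"] <-
    mean(pm_med[(nrow(pm_med) - 27L):nrow(pm_med), "END"]) / B
  out
}

observables_from_series <- function(series, B, eps) {
  out <- c()
  for (arm_id in names(series)) {
    med <- series[[arm_id]]
    restart <- attr(med, "restart_day")
    rel <- med[restart:nrow(med), "END"]
    is_case <- grepl("case", arm_id)
    cross <- if (is_case) {
      fractional_crossing(rel, B, strict = TRUE)
    } else {
      fractional_crossing(rel, (1 - eps) * B)
    }
    if (is.na(cross)) cross <- length(rel) + 100
    out[paste0("tt_", gsub("-", "_", arm_id))] <- cross
  }
  for (ph in c("EM", "IM")) {
    med <- series[[sprintf("B-%s-control-2wk", ph)]]
    out[paste0("ct_holiday_", ph, "_2wk")] <-
      med[attr(med, "restart_day"), "END"]
  }
  # the trough ratio is a pure-dynamics quantity: rescaling the endoxifen
  # volume moves both troughs together but never their ratio
  out["ratio_ct_holiday_IM_EM"] <-
    out[["ct_holiday_IM_2wk"]] / out[["ct_holiday_EM_2wk"]]
  im <- series[["A-IM-control"]]
  out["ratio_IM_control_ss"] <-
    mean(im[(nrow(im) - 27L):nrow(im), "END"]) / B
  out
}

## Dose matrices depend only on the calendar; cache them across the many
## objective evaluations of a calibration run.
.tx_cache <- new.env(parent = emptyenv())

cached_dose_matrices <- function(calendar) {
  key <- paste(calendar$run_in_days, calendar$intake_days, sep = "/")
  hit <- .tx_cache[[key]]
  if (!is.null(hit)) return(hit)
  arms <- enumerate_arms()
  protos <- lapply(arms, build_protocol, calendar = calendar)
  protos[["PM-combo"]] <- build_protocol(arm_spec("A", "EM", "case"), calendar)
  mats <- lapply(protos, function(p) {
    m <- protocol_dose_matrix(p)
    for (a in c("restart_day", "horizon_day")) attr(m, a) <- attr(p, a)
    m
  })
  # batch arms that share a propagator (phenotype) into one dose array
  groups <- list(EM = grep("EM", names(arms), value = TRUE),
                 IM = grep("IM", names(arms), value = TRUE),
                 PM = "PM-combo")
  batches <- lapply(groups, function(ids) {
    D <- max(vapply(mats[ids], ncol, 1L))
    doses <- array(0, dim = c(6L, length(ids), D))
    for (k in seq_along(ids)) {
      m <- mats[[ids[k]]]
      doses[, k, seq_len(ncol(m))] <- m
    }
    list(ids = ids, doses = doses, D = D,
         restart = vapply(mats[ids], attr, 1L, "restart_day"),
         horizon = vapply(mats[ids], attr, 1L, "horizon_day"))
  })
  out <- list(mats = mats, batches = batches)
  .tx_cache[[key]] <- out
  out
}

## Deterministic typical-patient observables: single-patient propagation per
## arm, no population sampling. Same conventions as the population path.
compute_typical_observables <- function(params, calendar = trial_calendar()) {
  eps <- params$eps_achieve
  doses_all <- cached_dose_matrices(calendar)
  prop <- list()
  for (ph in c("EM", "IM", "PM")) {
    A <- build_rate_matrix(params$network,
                           cyp2d6_activity(ph, params$theta[[ph]]))
    prop[[ph]] <- as.matrix(Matrix::expm(Matrix::Matrix(A)))
  }
  vols <- unlist(params$network[TX_VOLUMES])
  series <- list()
  for (ph in names(doses_all$batches)) {
    b <- doses_all$batches[[ph]]
    E <- prop[[ph]]
    narm <- length(b$ids)
    traj <- array(0, dim = c(b$D, 4L, narm))
    s <- matrix(0, 6L, narm)
    for (d in seq_len(b$D)) {
      traj[d, , ] <- s[3:6, ]
      s <- E %*% (s + b$doses[, , d])
    }
    for (k in seq_along(b$ids)) {
      med <- sweep(traj[seq_len(b$horizon[k]), , k], 2L, 1000 / vols, `*`)
      colnames(med) <- TX_COMPOUNDS
      attr(med, "restart_day") <- b$restart[k]
      attr(med, "horizon_day") <- b$horizon[k]
      series[[b$ids[k]]] <- med
    }
  }
  bench <- series[["A-EM-control"]]
  B <- mean(bench[(nrow(bench) - 27L):nrow(bench), "END"])
  pm <- series[["PM-combo"]]
  out <- observables_from_series(series[setdiff(names(series), "PM-combo")],
                                 B, eps)
  out["benchmark_median"] <- B
  out["benchmark_p25"] <- B
  out["ratio_PM_combo_ss"] <- mean(pm[(nrow(pm) - 27L):nrow(pm), "END"]) / B
  out
}

## ---- calibration targets and objective -----------------------------------

#' Calibration target
#'
#' A declared trial observable with its target value. `cmp = "eq"` targets
#' are two-sided; `cmp = "ge"` targets penalize only values below the bound
#' (used for day counts the source table reports as exceeding a limit).
#'
#' @param name Observable name (see [compute_trial_observables()]).
#' @param value Target value.
#' @param tolerance Residual scale: the residual is
#'   `(observed - value) / tolerance`.
#' @param weight Positive weight of the squared residual.
#' @param cmp `"eq"` (two-sided), `"ge"` (penalize only below the bound) or
#'   `"le"` (penalize only above it).
#' @param units Unit label (documentation only).
#' @return A one-row tibble.
#' @export
calibration_target <- function(name, value, tolerance, weight = 1,
                               cmp = c("eq", "ge", "le"), units = "") {
  cmp <- match.arg(cmp)
  if (weight <= 0) stop("weight must be > 0")
  if (tolerance <= 0) stop("tolerance must be > 0")
  tibble::tibble(name = name, value = value, tolerance = tolerance,
                 weight = weight, cmp = cmp, units = units)
}

#' Printed trial anchors used to calibrate the shipped parameter set
#'
#' Day-count anchors from the trial summary table (case: 9/13 and 2/5/8/9,
#' 4/7/10/11 days; control: 125/77 and 40/55/65/68 days; the EM post-holiday
#' control cells reported as exceeding 100 days enter as one-sided bounds),
#' the trough anchors after a 2-week holiday (14.9 and 10.6 ug/L), the
#' benchmark 25th percentile (13.8 ug/L), and the exposure-equalization
#' premise of the fixed-dose combinations (IM on 20 TAM + 1 END and PM on
#' 20 TAM + 3 END match the EM benchmark; the IM target carries a small
#' positive margin so the control arms cross their achievement threshold).
#' Day targets are expressed on the fractional-crossing convention of
#' [compute_trial_observables()].
#'
#' @param population Include the anchors that only exist at population level
#'   (`benchmark_p25`) — drop them when calibrating deterministically.
#' @return A tibble of [calibration_target()] rows.
#' @export
anchor_targets <- function(population = TRUE) {
  day <- function(name, d, mode, weight = 1) {
    calibration_target(name, if (mode == "case") d + 0.5 else d - 0.5,
                       tolerance = 1, weight = weight, units = "days")
  }
  tg <- rbind(
    day("tt_A_EM_case", 9, "case"),
    day("tt_A_EM_control", 125, "control"),
    day("tt_A_IM_case", 13, "case"),
    day("tt_A_IM_control", 77, "control"),
    day("tt_B_EM_case_2wk", 2, "case"),
    day("tt_B_EM_case_4wk", 5, "case"),
    day("tt_B_EM_case_8wk", 8, "case"),
    day("tt_B_EM_case_12wk", 9, "case"),
    day("tt_B_IM_case_2wk", 4, "case"),
    day("tt_B_IM_case_4wk", 7, "case"),
    day("tt_B_IM_case_8wk", 10, "case"),
    day("tt_B_IM_case_12wk", 11, "case"),
    day("tt_B_IM_control_2wk", 40, "control"),
    day("tt_B_IM_control_4wk", 55, "control"),
    day("tt_B_IM_control_8wk", 65, "control"),
    day("tt_B_IM_control_12wk", 68, "control"),
    # A post-holiday control arm of a linear system cannot recover later
    # than the from-zero arm reaches the same threshold (see the methods
    # vignette); the 126-day cell is kept at reduced weight and the
    # exceeds-100 cells as one-sided bounds.
    day("tt_B_EM_control_2wk", 126, "control", weight = 0.25),
    calibration_target("tt_B_EM_control_4wk", 101, 1, cmp = "ge", units = "days"),
    calibration_target("tt_B_EM_control_8wk", 101, 1, cmp = "ge", units = "days"),
    calibration_target("tt_B_EM_control_12wk", 101, 1, cmp = "ge", units = "days"),
    calibration_target("ct_holiday_EM_2wk", 14.9, 14.9 * 0.05, units = "ug/L"),
    calibration_target("ct_holiday_IM_2wk", 10.6, 10.6 * 0.05, units = "ug/L"),
    calibration_target("ratio_IM_control_ss", 1.025, 0.02),
    calibration_target("ratio_PM_combo_ss", 1.0, 0.05, weight = 0.5)
  )
  if (population) {
    tg <- rbind(tg,
                calibration_target("benchmark_p25", 13.8, 13.8 * 0.05,
                                   units = "ug/L"))
  }
  tg
}

#' Calibration loss
#'
#' Weighted sum of squared scaled residuals of the simulated observables
#' against the targets: `sum(w * ((obs - target) / tolerance)^2)`, with
#' one-sided (`cmp = "ge"`) targets contributing only when below the bound.
#' Simulation failures yield a large finite penalty so derivative-free
#' optimization can continue.
#'
#' @param par Named numeric vector of free parameters (fields of the
#'   kinetic set, `theta_IM`, `theta_PM`, `cv_clearance`, `cv_volume`).
#' @param targets Target tibble ([anchor_targets()] form).
#' @param base A `param_set` supplying every non-free value.
#' @param n Cohort size for the simulated observables (1 = deterministic).
#' @param seed Population seed.
#' @param calendar A [trial_calendar()].
#' @return Scalar loss with attribute `residuals` (per-target tibble).
#' @export
calibration_objective <- function(par, targets, base = default_parameters(),
                                  n = 1L, seed = 1L,
                                  calendar = trial_calendar()) {
  obs <- tryCatch(
    compute_trial_observables(apply_free_params(base, par), n = n,
                              seed = seed, calendar = calendar),
    error = function(e) {
      warning("simulation failed during calibration: ", conditionMessage(e))
      NULL
    })
  if (is.null(obs)) return(1e6)
  miss <- setdiff(targets$name, names(obs))
  if (length(miss) > 0L) stop("unknown observable(s): ", paste(miss, collapse = ", "))
  o <- obs[targets$name]
  r <- (o - targets$value) / targets$tolerance
  r[targets$cmp == "ge" & o >= targets$value] <- 0
  r[targets$cmp == "le" & o <= targets$value] <- 0
  loss <- sum(targets$weight * r^2)
  attr(loss, "residuals") <- tibble::tibble(
    name = targets$name, target = targets$value, observed = unname(o),
    residual = unname(r), weight = targets$weight, cmp = targets$cmp)
  loss
}

apply_free_params <- function(base, free) {
  ps <- base
  for (nm in names(free)) {
    if (nm == "theta_IM") ps$theta[["IM"]] <- free[[nm]]
    else if (nm == "theta_PM") ps$theta[["PM"]] <- free[[nm]]
    else if (nm == "cv_clearance") ps$cv$clearance <- free[[nm]]
    else if (nm == "cv_volume") ps$cv$volume <- free[[nm]]
    else if (nm %in% names(ps$network)) ps$network[[nm]] <- free[[nm]]
    else stop("unknown free parameter: ", nm)
  }
  validate_network_params(ps$network)
  ps
}

#' Calibrate free parameters against trial anchors
#'
#' Multistart bounded derivative-free minimization of
#' [calibration_objective()]: parameters are optimized on the log scale with
#' a quadratic penalty outside the bounds, from `n_starts` start points (the
#' base values plus log-uniform draws inside the bounds), each polished by
#' Nelder-Mead. Deterministic given `seed`.
#'
#' @param targets Target tibble ([anchor_targets()] form).
#' @param lower,upper Named bound vectors over the free parameters (equal
#'   lower and upper collapse that parameter to a fixed point).
#' @param seed Seed for start-point draws and population sampling.
#' @param base A `param_set` supplying non-free values.
#' @param n Cohort size per objective evaluation (1 = deterministic).
#' @param n_starts Number of starts.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param calendar A [trial_calendar()].
#' @return An object of class `calibration_result`: `params` (the fitted
#'   `param_set`), `par`, `loss`, `residuals`, `starts` (per-start log),
#'   `converged`, `seed`.
#' @export
calibrate <- function(targets, lower, upper, seed = 1L,
                      base = default_parameters(), n = 1L,
                      n_starts = 5L, maxit = 400L,
                      calendar = trial_calendar()) {
  if (nrow(targets) < 1L) stop("at least one calibration target is required")
  if (!identical(names(lower), names(upper))) {
    stop("lower and upper bounds must cover the same parameters")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower > upper) || any(lower <= 0)) {
    stop("bounds must be finite, positive and ordered")
  }
  free_names <- names(lower)
  llo <- log(lower); lup <- log(upper)

  penalized <- function(x) {
    over <- pmax(x - lup, 0) + pmax(llo - x, 0)
    par <- exp(pmin(pmax(x, llo), lup))
    names(par) <- free_names
    loss <- calibration_objective(par, targets, base = base, n = n,
                                  seed = seed, calendar = calendar)
    as.numeric(loss) + 1e3 * sum(over^2)
  }

  base_vals <- vapply(free_names, function(nm) {
    if (nm == "theta_IM") base$theta[["IM"]]
    else if (nm == "theta_PM") base$theta[["PM"]]
    else if (nm == "cv_clearance") base$cv$clearance
    else if (nm == "cv_volume") base$cv$volume
    else base$network[[nm]]
  }, numeric(1L))
  x0 <- log(pmin(pmax(base_vals, lower), upper))
  starts <- list(x0)
  if (n_starts > 1L) {
    with_seed(seed, {
      for (i in seq_len(n_starts - 1L)) {
        starts[[i + 1L]] <- llo + stats::runif(length(llo)) * (lup - llo)
      }
    })
  }

  fixed <- lup - llo < 1e-12
  best <- NULL
  log_rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    if (all(fixed)) {
      fit <- list(par = starts[[i]], value = penalized(starts[[i]]),
                  convergence = 0L)
    } else {
      # suppress the 1-parameter Nelder-Mead advisory; the quadratic bound
      # penalty keeps the simplex well behaved in that case too
      fit <- suppressWarnings(
        stats::optim(starts[[i]], penalized, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-8)))
    }
    log_rows[[i]] <- tibble::tibble(start = i, loss = fit$value,
                                    converged = fit$convergence == 0L)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("no calibration start converged")
  par <- exp(pmin(pmax(best$par, llo), lup))
  names(par) <- free_names
  loss <- calibration_objective(par, targets, base = base, n = n,
                                seed = seed, calendar = calendar)
  structure(list(params = apply_free_params(base, par), par = par,
                 loss = as.numeric(loss),
                 residuals = attr(loss, "residuals"),
                 starts = do.call(rbind, log_rows),
                 converged = best$convergence == 0L, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration result: loss %.4g over %d targets (seed %d)\n",
              x$loss, nrow(x$residuals), x$seed))
  print(as.data.frame(x$residuals), digits = 3)
  invisible(x)
}
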