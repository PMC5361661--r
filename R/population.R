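#' Specification of a virtual patient population
#'
#' Describes how to sample one cohort of virtual female patients of a single
#' CYP2D6 phenotype. Inter-individual variability is multiplicative
#' log-normal on every clearance (shared coefficient of variation
#' `cv_clearance`) and on every volume of distribution (`cv_volume`):
#' each realized parameter is `typical * exp(eps)` with
#' `eps ~ Normal(-sigma^2/2, sigma^2)` and `sigma^2 = log(1 + CV^2)`, so the
#' mean multiplicative factor is exactly 1.
#'
#' @param n Number of patients (>= 1).
#' @param phenotype CYP2D6 phenotype label, `"EM"`, `"IM"` or `"PM"`.
#' @param cv_clearance,cv_volume Coefficients of variation (>= 0).
#' @param seed Integer seed; sampling is bit-reproducible given the seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n, phenotype = c("EM", "IM", "PM"),
                            cv_clearance = 0.35, cv_volume = 0.20,
                            seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  if (cv_clearance < 0 || cv_volume < 0) stop("CVs must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer")
  }
  structure(list(n = as.integer(n), phenotype = phenotype,
                 cv_clearance = cv_clearance, cv_volume = cv_volume,
                 seed = as.integer(seed)),
            class = "population_spec")
}

## Run code with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Sample a virtual patient population
#'
#' Draws `spec$n` virtual patients around the typical parameter set.
#' Clearances and volumes receive independent patient-specific log-normal
#' factors (see [population_spec()]); absorption rate constants and
#' bioavailabilities are not varied. All patients carry the phenotype and
#' CYP2D6 activity multiplier of the spec.
#'
#' @param spec A [population_spec()].
#' @param typical A [network_params()] set of typical values.
#' @param theta Activity multiplier for the phenotype; defaults to the
#'   shipped calibrated value.
#' @return An object of class `pk_population`: list with `params` (an
#'   `n x 16` matrix of realized parameters, one row per patient), and the
#'   spec fields. Identical seeds give bit-identical draws.
#' @export
sample_population <- function(spec, typical, theta = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  validate_network_params(typical)
  if (is.null(theta)) theta <- default_parameters()$theta[[spec$phenotype]]
  n <- spec$n
  fields <- c("ka_TAM", "ka_END", "F_TAM", "F_END", TX_VOLUMES, TX_CLEARANCES)
  base <- matrix(rep(unlist(typical[fields]), each = n), nrow = n,
                 dimnames = list(NULL, fields))
  draw <- function(cv, k) {
    if (cv <= 0) return(matrix(1, n, k))
    s2 <- log(1 + cv^2)
    matrix(exp(stats::rnorm(n * k, mean = -s2 / 2, sd = sqrt(s2))), n, k)
  }
  with_seed(spec$seed, {
    base[, TX_CLEARANCES] <- base[, TX_CLEARANCES] *
      draw(spec$cv_clearance, length(TX_CLEARANCES))
    base[, TX_VOLUMES] <- base[, TX_VOLUMES] *
      draw(spec$cv_volume, length(TX_VOLUMES))
  })
  structure(list(params = base, n = n, phenotype = spec$phenotype,
                 theta = theta, cv_clearance = spec$cv_clearance,
                 cv_volume = spec$cv_volume, seed = spec$seed),
            class = "pk_population")
}

#' @export
print.pk_population <- function(x, ...) {
  cat(sprintf(
    "Virtual population: %d CYP2D6 %s patients (theta = %.3g)\n",
    x$n, x$phenotype, x$theta))
  cat(sprintf("  CV clearances %.2f, CV volumes %.2f, seed %d\n",
              x$cv_clearance, x$cv_volume, x$seed))
  invisible(x)
}

#' Extract one virtual patient
#'
#' @param population A `pk_population`.
#' @param i Patient index.
#' @return A list with `patient_id`, `phenotype`, `theta` and the realized
#'   [network_params()].
#' @export
get_individual <- function(population, i) {
  stopifnot(inherits(population, "pk_population"))
  if (i < 1L || i > population$n) stop("patient index out of range")
  prm <- as.list(population$params[i, ])
  list(patient_id = i, phenotype = population$phenotype,
       theta = population$theta,
       params = structure(prm, class = "network_params"))
}

#' Export or import a population as one row per patient
#'
#' `population_to_df()` flattens the realized draws for CSV reproducibility
#' audits; `population_from_df()` rebuilds an equivalent population object
#' from such a table (draw provenance is recorded as absent).
#'
#' @param population A `pk_population`.
#' @return A tibble with `patient_id`, `phenotype`, `theta` and one column
#'   per realized parameter.
#' @export
population_to_df <- function(population) {
  stopifnot(inherits(population, "pk_population"))
  tibble::as_tibble(cbind(
    data.frame(patient_id = seq_len(population$n),
               phenotype = population$phenotype,
               theta = population$theta),
    as.data.frame(population$params)
  ))
}

#' @rdname population_to_df
#' @param df A data frame in the layout written by `population_to_df()`.
#' @export
population_from_df <- function(df) {
  fields <- c("ka_TAM", "ka_END", "F_TAM", "F_END", TX_VOLUMES, TX_CLEARANCES)
  missing <- setdiff(c("phenotype", "theta", fields), names(df))
  if (length(missing) > 0L) {
    stop("population table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  params <- as.matrix(df[, fields])
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("realized parameters must be positive")
  }
  structure(list(params = params, n = nrow(df),
                 phenotype = df$phenotype[1L], theta = df$theta[1L],
                 cv_clearance = NA_real_, cv_volume = NA_real_,
                 seed = NA_integer_),
            class = "pk_population")
}
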