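#' Scenario parameters for the migrant-influx simulation
#'
#' Constructs and validates the full configuration of one stochastic
#' scenario: city geometry, tolerance levels, the entry process and the
#' run length. Defaults are the reference configuration used throughout
#' the package: a city of 20 neighbourhoods and 1000 residents with
#' resident tolerance 0.25, migrant tolerance 0.75, entry friction
#' `beta_in = 1`, a population cap at 150% of the initial population and
#' 200 iterations.
#'
#' @param g Entry rate: the fraction of the current city population that
#'   attempts entry at each iteration (`Mig(t) = g * P(t-1)`).
#' @param M Number of neighbourhoods (cells).
#' @param n_residents Number of resident agents; must be divisible by `M`
#'   so every cell starts with `n_residents / M` residents.
#' @param tau_res Resident tolerance: the maximum fraction of migrants in
#'   a neighbourhood a resident accepts before attempting to move.
#' @param tau_mig Migrant tolerance: the maximum fraction of residents in
#'   a neighbourhood a migrant accepts before attempting to move.
#' @param beta_in Nonnegative entry friction. A migrant drawn to cell `i`
#'   is admitted with probability `exp(-beta_in * resident_fraction(i))`.
#' @param max_pop_factor Population cap as a multiple of the initial
#'   population; once `P(t-1)` reaches `max_pop_factor * P(0)` no further
#'   migrants attempt entry.
#' @param n_iterations Number of iterations to simulate.
#' @param seed Integer seed used by [run_simulation()]; `NA` leaves the
#'   random number generator untouched.
#' @param move_with_replacement If `TRUE` (default) the movement phase
#'   draws `P(t)` agents uniformly with replacement, so every agent is
#'   sampled once per iteration on average. If `FALSE` a random
#'   permutation of all agents is processed instead.
#' @param census_breach_marking If `TRUE`, an end-of-iteration census
#'   additionally marks every resident sitting in a breached cell as
#'   ever-breached. By default breaches are recorded only when an agent
#'   is activated during the movement phase and finds its tolerance
#'   breached (see the package vignette for the rationale).
#'
#' @return An object of class `model_params`: a validated named list.
#' @seealso [run_simulation()], [run_ensemble()], [default_scenarios()]
#' @examples
#' p <- model_params(g = 0.01)
#' p
#' @export
model_params <- function(g,
                         M = 20L,
                         n_residents = 1000L,
                         tau_res = 0.25,
                         tau_mig = 0.75,
                         beta_in = 1,
                         max_pop_factor = 1.5,
                         n_iterations = 200L,
                         seed = 1L,
                         move_with_replacement = TRUE,
                         census_breach_marking = FALSE) {
  p <- list(
    M = as.integer(M),
    n_residents = as.integer(n_residents),
    tau_res = as.numeric(tau_res),
    tau_mig = as.numeric(tau_mig),
    g = as.numeric(g),
    beta_in = as.numeric(beta_in),
    max_pop_factor = as.numeric(max_pop_factor),
    n_iterations = as.integer(n_iterations),
    seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
    move_with_replacement = isTRUE(move_with_replacement),
    census_breach_marking = isTRUE(census_breach_marking)
  )
  class(p) <- "model_params"
  validate_model_params(p)
}

#' @rdname model_params
#' @param x A `model_params` object.
#' @export
validate_model_params <- function(x) {
  stopifnot(inherits(x, "model_params"))
  with(x, {
    if (!is.finite(M) || M < 1L) stop("'M' must be a positive integer")
    if (!is.finite(n_residents) || n_residents < 1L)
      stop("'n_residents' must be a positive integer")
    if (n_residents %% M != 0L)
      stop("'n_residents' (", n_residents, ") must be divisible by 'M' (",
           M, ") so that initial cells are equal")
    if (is.na(tau_res) || tau_res < 0 || tau_res > 1)
      stop("'tau_res' must lie in [0, 1]")
    if (is.na(tau_mig) || tau_mig < 0 || tau_mig > 1)
      stop("'tau_mig' must lie in [0, 1]")
    if (is.na(g) || g < 0) stop("'g' must be a nonnegative fraction")
    if (is.na(beta_in) || beta_in < 0) stop("'beta_in' must be >= 0")
    if (is.na(max_pop_factor) || max_pop_factor < 1)
      stop("'max_pop_factor' must be >= 1")
    if (!is.finite(n_iterations) || n_iterations < 0L)
      stop("'n_iterations' must be a nonnegative integer")
  })
  x
}

#' @export
print.model_params <- function(x, ...) {
  cat("Migrant-influx scenario parameters\n")
  cat(sprintf("  neighbourhoods (M)       : %d\n", x$M))
  cat(sprintf("  resident agents          : %d (%d per cell)\n",
              x$n_residents, x$n_residents %/% x$M))
  cat(sprintf("  tolerances (res / mig)   : %.3g / %.3g\n", x$tau_res, x$tau_mig))
  cat(sprintf("  entry rate g             : %.4g\n", x$g))
  cat(sprintf("  entry friction beta_in   : %.3g\n", x$beta_in))
  cat(sprintf("  population cap           : %.0f%% of initial\n",
              100 * x$max_pop_factor))
  cat(sprintf("  iterations               : %d\n", x$n_iterations))
  cat(sprintf("  seed                     : %s\n", format(x$seed)))
  if (!x$move_with_replacement)
    cat("  movement sampling        : permutation (without replacement)\n")
  if (x$census_breach_marking)
    cat("  breach marking           : activation + end-of-iteration census\n")
  invisible(x)
}

#' Read and write scenario parameters as flat YAML or JSON
#'
#' Parameters serialize to a flat mapping with the canonical key names
#' `M`, `n_residents`, `tau_res`, `tau_mig`, `g`, `beta_in`,
#' `max_pop_factor`, `n_iterations`, `seed` (plus the two engine
#' toggles). The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param params A [model_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_model_params()` returns `path` invisibly;
#'   `read_model_params()` returns a `model_params` object.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  flat <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(flat, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unrecognised parameter file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  flat <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unrecognised parameter file extension: ", path)
  }
  known <- names(formals(model_params))
  do.call(model_params, flat[intersect(names(flat), known)])
}
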