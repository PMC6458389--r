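#' Initialise a city state
#'
#' Builds the initial city: `M` cells each holding `n_residents / M`
#' resident agents, no migrants, iteration counter at zero and no breach
#' history. The returned object has reference semantics (it is an
#' environment): the engine functions [entry_phase()], [attempt_move()],
#' [movement_phase()] and [sim_step()] update it in place.
#'
#' Residents are identifiable agents (indices `1..n_residents`) whose
#' cell, ever-breached flag and first-breach iteration are tracked
#' individually. Migrants are identifiable from the moment they are
#' admitted (indices grow as migrants enter) but carry no breach
#' history, since only resident tolerance breaches are observables.
#'
#' @param params A [model_params()] object; `n_residents` must be
#'   divisible by `M`.
#' @return An object of class `city_state`.
#' @examples
#' st <- init_city(model_params(g = 0.01))
#' st
#' @export
init_city <- function(params) {
  validate_model_params(params)
  M <- params$M
  n_res <- params$n_residents
  st <- new.env(parent = emptyenv())
  st$M <- M
  st$n_res <- n_res
  st$P0 <- n_res
  st$res_cell <- rep(seq_len(M), each = n_res %/% M)
  st$res_count <- tabulate(st$res_cell, M)
  st$mig_cell <- integer(0)
  st$mig_count <- integer(M)
  st$ever_breached <- logical(n_res)
  st$first_breach <- rep(NA_integer_, n_res)
  st$t <- 0L
  st$entry_log <- list()
  class(st) <- "city_state"
  st
}

#' Total population of the city
#' @param state A [init_city()] state.
#' @return Integer count of residents plus admitted migrants.
#' @export
city_population <- function(state) {
  state$n_res + length(state$mig_cell)
}

#' Composition of one cell
#'
#' Resident and migrant counts and fractions for cell `i`. Fractions are
#' counts over the cell total; for an empty cell both fractions are
#' defined as 0, so an empty cell satisfies any tolerance level and is
#' always an acceptable destination.
#'
#' @param state A [init_city()] state.
#' @param i Cell index in `1..M`.
#' @return Named numeric vector with elements `residents`, `migrants`,
#'   `resident_frac`, `migrant_frac`.
#' @export
cell_composition <- function(state, i) {
  if (length(i) != 1L || is.na(i) || i < 1L || i > state$M)
    stop("invalid cell index: ", i)
  r <- state$res_count[i]
  m <- state$mig_count[i]
  tot <- r + m
  c(residents = r, migrants = m,
    resident_frac = if (tot == 0L) 0 else r / tot,
    migrant_frac = if (tot == 0L) 0 else m / tot)
}

#' Tolerance satisfaction predicate
#'
#' An agent is satisfied when the fraction of opposite-type agents in
#' its cell does not exceed its tolerance level: the tolerance is the
#' maximum opposite-type fraction the agent is willing to accept, so
#' boundary equality counts as satisfied and a breach is a strict
#' exceedance. Vectorised over `opposite_fraction`.
#'
#' @param agent_type `"resident"` or `"migrant"`.
#' @param opposite_fraction Fraction(s) in `[0, 1]` of the opposite type
#'   in the agent's cell (migrant fraction for residents, resident
#'   fraction for migrants).
#' @param params A [model_params()] object supplying `tau_res` and
#'   `tau_mig`.
#' @return Logical vector: `TRUE` where satisfied.
#' @export
is_satisfied <- function(agent_type, opposite_fraction, params) {
  agent_type <- match.arg(agent_type, c("resident", "migrant"))
  if (any(opposite_fraction < 0 | opposite_fraction > 1, na.rm = TRUE))
    stop("'opposite_fraction' must lie in [0, 1]")
  tau <- if (agent_type == "resident") params$tau_res else params$tau_mig
  opposite_fraction <= tau
}

#' Agent table of a city state
#'
#' One row per agent, residents first (ids `1..n_residents`) then
#' migrants in order of admission. Cells are reported 1-based;
#' first-breach iterations are 1-based time steps.
#'
#' @param state A [init_city()] state.
#' @return A data frame with columns `agent_id`, `agent_type`, `cell`,
#'   `ever_breached`, `first_breach_iteration`.
#' @export
city_agents <- function(state) {
  n_mig <- length(state$mig_cell)
  data.frame(
    agent_id = seq_len(state$n_res + n_mig),
    agent_type = rep(c("resident", "migrant"), c(state$n_res, n_mig)),
    cell = c(state$res_cell, state$mig_cell),
    ever_breached = c(state$ever_breached, rep(NA, n_mig)),
    first_breach_iteration = c(state$first_breach, rep(NA_integer_, n_mig))
  )
}

#' @export
print.city_state <- function(x, ...) {
  cat(sprintf("City state at iteration %d: %d cells, %d residents, %d migrants\n",
              x$t, x$M, x$n_res, length(x$mig_cell)))
  cat(sprintf("  residents ever breached: %d (%.2f%%)\n",
              sum(x$ever_breached), 100 * mean(x$ever_breached)))
  comp <- rbind(residents = x$res_count, migrants = x$mig_count)
  colnames(comp) <- seq_len(x$M)
  print(comp)
  invisible(x)
}

# Internal: strict-exceedance breach test on integer counts.
# opp > tau * tot  <=>  opposite fraction strictly above tolerance.
.breached_counts <- function(opp, tot, tau) {
  tot > 0L & opp > tau * tot
}
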