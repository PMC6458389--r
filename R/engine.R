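#' Number of migrants attempting entry at an iteration
#'
#' `Mig(t) = g * P(t-1)`, rounded half-up to an integer, with the
#' population cap applied: once the previous population has reached
#' `max_pop_factor * P(0)`, zero migrants attempt to enter.
#'
#' @param prev_population City population at the end of the previous
#'   iteration, `P(t-1)`.
#' @param initial_population Initial population `P(0)`.
#' @param params A [model_params()] object.
#' @return Integer count of attempting migrants.
#' @export
attempted_migrants <- function(prev_population, initial_population, params) {
  stopifnot(prev_population >= initial_population, initial_population >= 1)
  if (prev_population >= params$max_pop_factor * initial_population)
    return(0L)
  as.integer(floor(params$g * prev_population + 0.5))
}

#' Probability that a migrant enters a cell
#'
#' `exp(-beta_in * resident_fraction)`: entry is easiest into cells with
#' few residents (probability 1 when the cell has no residents) and
#' hardest into all-resident cells. With `beta_in = 0` every attempt
#' succeeds; as `beta_in` grows large no migrants enter. Vectorised
#' over `resident_fraction`.
#'
#' @param resident_fraction Fraction(s) in `[0, 1]` of residents in the
#'   target cell.
#' @param beta_in Nonnegative friction parameter.
#' @return Entry probabilities in `(0, 1]`.
#' @export
entry_probability <- function(resident_fraction, beta_in) {
  if (length(beta_in) != 1L || is.na(beta_in) || beta_in < 0)
    stop("'beta_in' must be a single nonnegative number")
  if (any(resident_fraction < 0 | resident_fraction > 1, na.rm = TRUE))
    stop("'resident_fraction' must lie in [0, 1]")
  exp(-beta_in * resident_fraction)
}

#' Migrant entry phase of one iteration
#'
#' For each of the `Mig(t)` attempting migrants, sequentially: draw a
#' target cell uniformly at random, compute the entry probability from
#' that cell's current resident fraction, and admit the migrant with
#' that probability. Admitted migrants are added to the cell
#' immediately, so later attempts in the same iteration see the updated
#' composition; failed attempts are discarded (one draw, no retry).
#' The state is modified in place and the per-iteration statistics are
#' appended to `state$entry_log`.
#'
#' @param state A [init_city()] state (updated in place).
#' @param params A [model_params()] object.
#' @return Invisibly, a list with elements `attempted`, `admitted` and
#'   `entry_probabilities` (one probability per attempt).
#' @export
entry_phase <- function(state, params) {
  n_att <- attempted_migrants(city_population(state), state$P0, params)
  probs <- numeric(n_att)
  admitted <- 0L
  if (n_att > 0L) {
    cells <- sample.int(state$M, n_att, replace = TRUE)
    for (k in seq_len(n_att)) {
      i <- cells[k]
      tot <- state$res_count[i] + state$mig_count[i]
      fr <- if (tot == 0L) 0 else state$res_count[i] / tot
      p <- exp(-params$beta_in * fr)
      probs[k] <- p
      if (stats::runif(1) < p) {
        state$mig_count[i] <- state$mig_count[i] + 1L
        state$mig_cell <- c(state$mig_cell, i)
        admitted <- admitted + 1L
      }
    }
  }
  stats_k <- list(attempted = n_att, admitted = admitted,
                  entry_probabilities = probs)
  state$entry_log[[length(state$entry_log) + 1L]] <- stats_k
  invisible(stats_k)
}

#' One movement attempt by one agent
#'
#' The classic relocation rule: the agent stays put if it is satisfied
#' with its current cell. If its tolerance is breached, a candidate cell
#' `j` different from its current cell is drawn uniformly at random and
#' the agent moves there if and only if it would be satisfied in `j`
#' evaluated with itself included; otherwise it stays. A resident that
#' finds its tolerance breached here is marked ever-breached with the
#' current iteration as its first-breach time (if not already marked).
#'
#' @param state A [init_city()] state (updated in place).
#' @param agent Agent index in `1..P(t)`: residents are `1..n_residents`,
#'   migrants follow in order of admission.
#' @param params A [model_params()] object.
#' @return `TRUE` if the agent moved, else `FALSE`.
#' @export
attempt_move <- function(state, agent, params) {
  M <- state$M
  if (agent <= state$n_res) {
    i <- state$res_cell[agent]
    if (state$mig_count[i] > params$tau_res * (state$res_count[i] + state$mig_count[i])) {
      if (!state$ever_breached[agent]) {
        state$ever_breached[agent] <- TRUE
        state$first_breach[agent] <- max(state$t, 1L)
      }
      j <- sample.int(M - 1L, 1L)
      if (j >= i) j <- j + 1L
      if (state$mig_count[j] <= params$tau_res * (state$res_count[j] + state$mig_count[j] + 1L)) {
        state$res_cell[agent] <- j
        state$res_count[i] <- state$res_count[i] - 1L
        state$res_count[j] <- state$res_count[j] + 1L
        return(TRUE)
      }
    }
  } else {
    m <- agent - state$n_res
    if (m > length(state$mig_cell)) stop("no such agent: ", agent)
    i <- state$mig_cell[m]
    if (state$res_count[i] > params$tau_mig * (state$res_count[i] + state$mig_count[i])) {
      j <- sample.int(M - 1L, 1L)
      if (j >= i) j <- j + 1L
      if (state$res_count[j] <= params$tau_mig * (state$res_count[j] + state$mig_count[j] + 1L)) {
        state$mig_cell[m] <- j
        state$mig_count[i] <- state$mig_count[i] - 1L
        state$mig_count[j] <- state$mig_count[j] + 1L
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Movement phase of one iteration
#'
#' Draws `P(t)` agents uniformly at random with replacement (so each
#' agent is activated once per iteration on average; set
#' `move_with_replacement = FALSE` in the parameters for a full random
#' permutation instead) and processes each draw sequentially with
#' [attempt_move()], updating the state after every action.
#'
#' @param state A [init_city()] state (updated in place).
#' @param params A [model_params()] object.
#' @return Invisibly, the number of moves that took place.
#' @export
movement_phase <- function(state, params) {
  P <- city_population(state)
  draws <- if (params$move_with_replacement)
    sample.int(P, P, replace = TRUE)
  else
    sample.int(P)
  # Inlined relocation rule, identical to attempt_move() draw for draw
  # (verified by an equivalence test); hoisting the parameter lookups out
  # of the per-agent loop is what makes full-length runs cheap.
  M <- state$M
  n_res <- state$n_res
  tau_res <- params$tau_res
  tau_mig <- params$tau_mig
  t_now <- max(state$t, 1L)
  res_cell <- state$res_cell
  mig_cell <- state$mig_cell
  res_count <- state$res_count
  mig_count <- state$mig_count
  ever <- state$ever_breached
  first <- state$first_breach
  n_moves <- 0L
  for (a in draws) {
    if (a <= n_res) {
      i <- res_cell[a]
      if (mig_count[i] > tau_res * (res_count[i] + mig_count[i])) {
        if (!ever[a]) {
          ever[a] <- TRUE
          first[a] <- t_now
        }
        j <- sample.int(M - 1L, 1L)
        if (j >= i) j <- j + 1L
        if (mig_count[j] <= tau_res * (res_count[j] + mig_count[j] + 1L)) {
          res_cell[a] <- j
          res_count[i] <- res_count[i] - 1L
          res_count[j] <- res_count[j] + 1L
          n_moves <- n_moves + 1L
        }
      }
    } else {
      i <- mig_cell[a - n_res]
      if (res_count[i] > tau_mig * (res_count[i] + mig_count[i])) {
        j <- sample.int(M - 1L, 1L)
        if (j >= i) j <- j + 1L
        if (res_count[j] <= tau_mig * (res_count[j] + mig_count[j] + 1L)) {
          mig_cell[a - n_res] <- j
          mig_count[i] <- mig_count[i] - 1L
          mig_count[j] <- mig_count[j] + 1L
          n_moves <- n_moves + 1L
        }
      }
    }
  }
  state$res_cell <- res_cell
  state$mig_cell <- mig_cell
  state$res_count <- res_count
  state$mig_count <- mig_count
  state$ever_breached <- ever
  state$first_breach <- first
  invisible(n_moves)
}

# Internal: end-of-iteration census. Computes the observables from the
# current cell compositions and (optionally) marks residents of breached
# cells as ever-breached.
.census <- function(state, params, entry_stats = NULL, prev_population = NA) {
  tot <- state$res_count + state$mig_count
  breached_cells <- .breached_counts(state$mig_count, tot, params$tau_res)
  if (params$census_breach_marking && state$t > 0L) {
    newly <- !state$ever_breached & breached_cells[state$res_cell]
    if (any(newly)) {
      state$ever_breached[newly] <- TRUE
      state$first_breach[newly] <- state$t
    }
  }
  P <- city_population(state)
  data.frame(
    t = state$t,
    population = P,
    migrants = length(state$mig_cell),
    attempted = if (is.null(entry_stats)) NA_integer_ else entry_stats$attempted,
    admitted = if (is.null(entry_stats)) NA_integer_ else entry_stats$admitted,
    mean_entry_prob = if (is.null(entry_stats) || entry_stats$attempted == 0L)
      NA_real_ else mean(entry_stats$entry_probabilities),
    B_c = sum(state$res_count[breached_cells]) / state$n_res,
    B_f = mean(state$ever_breached),
    CSI = csi(state),
    growth_rate = if (is.na(prev_population)) NA_real_
      else (P - prev_population) / prev_population
  )
}

#' Advance the simulation by one iteration
#'
#' Runs the entry phase, then the movement phase, then an
#' end-of-iteration census that computes all observables (and, when
#' `census_breach_marking` is enabled, marks residents currently in
#' breached cells as ever-breached). The iteration counter is advanced;
#' iterations are 1-based.
#'
#' @param state A [init_city()] state (updated in place).
#' @param params A [model_params()] object.
#' @return A one-row data frame of per-iteration observables: `t`,
#'   `population`, `migrants`, `attempted`, `admitted`,
#'   `mean_entry_prob`, `B_c`, `B_f`, `CSI`, `growth_rate`.
#' @export
sim_step <- function(state, params) {
  prev <- city_population(state)
  state$t <- state$t + 1L
  es <- entry_phase(state, params)
  movement_phase(state, params)
  .census(state, params, entry_stats = es, prev_population = prev)
}

#' Run one seeded simulation
#'
#' Initialises the city, seeds the random number generator from
#' `params$seed` (the global RNG state is restored on exit) and runs
#' `n_iterations` steps. The same parameters and seed always reproduce
#' the identical trajectory.
#'
#' @param params A [model_params()] object.
#' @param run_id Identifier stored in the trajectory (used by
#'   [run_ensemble()]).
#' @return An object of class `tolerance_sim`: a list with elements
#'   * `params`: the scenario parameters;
#'   * `trajectory`: data frame with the initial census (`t = 0`) and one
#'     row per iteration, columns `run_id`, `seed`, `g`, `t`,
#'     `population`, `migrants`, `attempted`, `admitted`,
#'     `mean_entry_prob`, `B_c`, `B_f`, `CSI`, `growth_rate`;
#'   * `breach_table`: data frame (`agent_id`, `first_breach_iteration`)
#'     of residents ever breached;
#'   * `state`: the final [init_city()] state.
#' @examples
#' sim <- run_simulation(model_params(g = 0.05, n_iterations = 50, seed = 7))
#' sim
#' @export
run_simulation <- function(params, run_id = 1L) {
  validate_model_params(params)
  if (!is.na(params$seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old_seed))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(params$seed)
  }
  state <- init_city(params)
  rows <- vector("list", params$n_iterations + 1L)
  rows[[1L]] <- .census(state, params)
  for (k in seq_len(params$n_iterations))
    rows[[k + 1L]] <- sim_step(state, params)
  traj <- do.call(rbind, rows)
  traj <- cbind(run_id = run_id, seed = params$seed, g = params$g, traj)
  rownames(traj) <- NULL
  breached <- which(state$ever_breached)
  structure(
    list(params = params,
         trajectory = traj,
         breach_table = data.frame(
           agent_id = breached,
           first_breach_iteration = state$first_breach[breached]),
         state = state),
    class = "tolerance_sim")
}

#' @export
print.tolerance_sim <- function(x, ...) {
  tr <- x$trajectory
  fin <- tr[nrow(tr), ]
  cat(sprintf("Migrant-influx simulation: g = %.4g, %d iterations, seed %s\n",
              x$params$g, x$params$n_iterations, format(x$params$seed)))
  cat(sprintf("  final population : %d (+%.1f%% of initial)\n", fin$population,
              100 * (fin$population - x$state$P0) / x$state$P0))
  cat(sprintf("  final B_f        : %.2f%% (%d residents ever breached)\n",
              100 * fin$B_f, nrow(x$breach_table)))
  cat(sprintf("  final B_c        : %.2f%%\n", 100 * fin$B_c))
  cat(sprintf("  final CSI        : %.3f\n", fin$CSI))
  if (nrow(x$breach_table) > 0L)
    cat(sprintf("  first breach at t = %d; mean time to first breach T_tau = %.1f\n",
                min(x$breach_table$first_breach_iteration),
                mean(x$breach_table$first_breach_iteration)))
  invisible(x)
}

#' @export
summary.tolerance_sim <- function(object, ...) {
  tr <- object$trajectory
  fin <- tr[nrow(tr), ]
  bt <- object$breach_table
  out <- list(
    g = object$params$g,
    seed = object$params$seed,
    n_iterations = object$params$n_iterations,
    final_population = fin$population,
    population_increase = (fin$population - object$state$P0) / object$state$P0,
    final_B_f = fin$B_f,
    peak_B_c = max(tr$B_c),
    final_CSI = fin$CSI,
    n_breached = nrow(bt),
    first_breach_time = if (nrow(bt)) min(bt$first_breach_iteration) else NA_real_,
    T_tau = if (nrow(bt)) mean(bt$first_breach_iteration) else NA_real_
  )
  class(out) <- "summary.tolerance_sim"
  out
}

#' @export
print.summary.tolerance_sim <- function(x, ...) {
  cat(sprintf("g = %.4g (seed %s): final B_f = %.2f%%, peak B_c = %.2f%%, ",
              x$g, format(x$seed), 100 * x$final_B_f, 100 * x$peak_B_c))
  cat(sprintf("T_tau = %s, first breach = %s, pop +%.1f%%\n",
              ifelse(is.na(x$T_tau), "-", sprintf("%.1f", x$T_tau)),
              ifelse(is.na(x$first_breach_time), "-", x$first_breach_time),
              100 * x$population_increase))
  invisible(x)
}

#' @export
as.data.frame.tolerance_sim <- function(x, ...) x$trajectory

#' @export
plot.tolerance_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(tr$t, tr$population, type = "l", xlab = "t", ylab = "population",
       main = sprintf("g = %.4g", x$params$g), ...)
  plot(tr$t, 100 * tr$B_c, type = "l", xlab = "t", ylab = "B_c (%)",
       main = "current breach", ...)
  plot(tr$t, 100 * tr$B_f, type = "l", xlab = "t", ylab = "B_f (%)",
       main = "ever breached", ...)
  plot(tr$t, tr$CSI, type = "l", ylim = c(0, 1), xlab = "t", ylab = "CSI",
       main = "segregation", ...)
  invisible(x)
}
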