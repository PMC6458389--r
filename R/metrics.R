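#' Current fraction of breached residents
#'
#' Share of residents whose tolerance is breached by the composition of
#' their current cell, evaluated on the present cell compositions
#' (`R_cb(t) / R_tot`). Because tolerances are homogeneous, every
#' resident of a breached cell is breached, so the count is a sum of
#' resident counts over breached cells.
#'
#' @param state A [init_city()] state.
#' @param params A [model_params()] object.
#' @return Fraction in `[0, 1]`.
#' @export
current_breach_fraction <- function(state, params) {
  tot <- state$res_count + state$mig_count
  breached <- .breached_counts(state$mig_count, tot, params$tau_res)
  sum(state$res_count[breached]) / state$n_res
}

#' Fraction of residents ever breached
#'
#' Share of residents whose tolerance has been breached at any point so
#' far (`R_b(t) / R_tot`); nondecreasing over a run since breach flags
#' never clear.
#'
#' @param state A [init_city()] state.
#' @return Fraction in `[0, 1]`.
#' @export
ever_breached_fraction <- function(state) {
  mean(state$ever_breached)
}

#' Mean time to first tolerance breach
#'
#' Arithmetic mean of the first-breach iteration over all residents ever
#' breached (`T_tau`). Undefined when no resident has been breached:
#' this is signalled as an error rather than returned as 0.
#'
#' @param x A `tolerance_sim` object, a breach table as returned in
#'   `run_simulation()$breach_table`, or a numeric vector of first-breach
#'   iterations.
#' @return Mean first-breach time in iterations.
#' @export
mean_time_to_first_breach <- function(x) {
  times <- if (inherits(x, "tolerance_sim")) x$breach_table$first_breach_iteration
  else if (is.data.frame(x)) x$first_breach_iteration
  else x
  times <- times[!is.na(times)]
  if (length(times) == 0L)
    stop("mean time to first breach is undefined: no resident was ever breached")
  mean(times)
}

#' Cell segregation indicator (CSI)
#'
#' Mean over non-empty cells of `|f_r(i) - f_m(i)| / (f_r(i) + f_m(i))`,
#' where `f_r(i)` and `f_m(i)` are the cell's shares of the city-wide
#' resident and migrant totals. CSI is 1 when every non-empty cell holds
#' a single type (full segregation) and 0 when every cell holds equal
#' shares of both totals (proportional mixing). While the city holds no
#' migrants, `f_m(i)` is taken as 0 for all cells, so the indicator is
#' defined (and equals 1) from the initial state onwards.
#'
#' @param state A [init_city()] state, or a list with integer vectors
#'   `res_count` and `mig_count` (per-cell counts).
#' @return Value in `[0, 1]`.
#' @export
csi <- function(state) {
  r <- state$res_count
  m <- state$mig_count
  n_r <- sum(r)
  n_m <- sum(m)
  if (n_r + n_m == 0L) stop("CSI is undefined: the city is empty")
  f_r <- if (n_r > 0L) r / n_r else rep(0, length(r))
  f_m <- if (n_m > 0L) m / n_m else rep(0, length(m))
  keep <- (r + m) > 0L
  mean(abs(f_r[keep] - f_m[keep]) / (f_r[keep] + f_m[keep]))
}

# Internal: per-iteration observable frame of a run or an ensemble
# (ensemble rows are cross-run means at fixed t).
.obs_frame <- function(x) {
  if (inherits(x, "tolerance_sim")) x$trajectory
  else if (inherits(x, "tolerance_ensemble")) x$mean
  else if (is.data.frame(x)) x
  else stop("expected a tolerance_sim, tolerance_ensemble or trajectory data frame")
}

#' Per-iteration population growth rate
#'
#' `(P(t) - P(t-1)) / P(t-1)` per iteration. For an ensemble the rate is
#' computed on the cross-run mean population path. `window` selects an
#' iteration range and returns the mean rate over it; `window = "precap"`
#' uses the growth window ending at the last iteration with nonzero
#' admissions (after which the population cap makes the rate 0).
#'
#' @param x A `tolerance_sim`, `tolerance_ensemble` or trajectory data
#'   frame.
#' @param window `NULL` for the full per-iteration vector, a length-2
#'   integer range, or `"precap"`.
#' @return Named numeric vector of rates (names are iterations), or a
#'   single mean rate when `window` is given.
#' @export
periodic_growth_rate <- function(x, window = NULL) {
  tr <- .obs_frame(x)
  tr <- tr[order(tr$t), ]
  pop <- tr$population
  rate <- diff(pop) / pop[-length(pop)]
  names(rate) <- tr$t[-1L]
  if (is.null(window)) return(rate)
  if (identical(window, "precap")) {
    adm <- tr$admitted[-1L]
    last_entry <- if (any(adm > 0, na.rm = TRUE))
      max(which(adm > 0)) else length(rate)
    window <- c(1L, last_entry)
  }
  mean(rate[window[1L]:window[2L]])
}

#' Iterations needed to reach whole-percent breach levels
#'
#' For each whole-percent level of the ever-breached fraction `B_f`, the
#' first iteration at which the (ensemble-mean) `B_f` reaches that
#' level. The 0% row reports the first-breach time: the first iteration
#' with `B_f > 0`. Levels never attained are absent.
#'
#' @param x A `tolerance_sim`, `tolerance_ensemble` or trajectory data
#'   frame.
#' @param levels Percent levels to tabulate; defaults to 0 up to the
#'   maximum attained whole percent.
#' @return Data frame with columns `level_pct` and `t_first`.
#' @export
time_per_breach_percent <- function(x, levels = NULL) {
  tr <- .obs_frame(x)
  tr <- tr[order(tr$t), ]
  if (is.null(levels)) levels <- 0:floor(100 * max(tr$B_f))
  rows <- lapply(levels, function(L) {
    idx <- if (L == 0) which(tr$B_f > 0)[1L]
    else which(tr$B_f >= L / 100)[1L]
    if (is.na(idx)) NULL
    else data.frame(level_pct = L, t_first = tr$t[idx])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(level_pct = numeric(0), t_first = numeric(0))
  else out
}

#' Population increase at whole-percent breach levels
#'
#' For each whole-percent level of `B_f` attained, the relative
#' population increase `(P(t*) - P(0)) / P(0)` at the first iteration
#' `t*` where the (ensemble-mean) `B_f` reaches the level.
#'
#' @inheritParams time_per_breach_percent
#' @return Data frame with columns `level_pct`, `t_first`,
#'   `pop_increase`.
#' @export
breach_vs_population_curve <- function(x, levels = NULL) {
  tr <- .obs_frame(x)
  tr <- tr[order(tr$t), ]
  if (is.null(levels)) levels <- 0:floor(100 * max(tr$B_f))
  P0 <- tr$population[1L]
  rows <- lapply(levels, function(L) {
    idx <- which(tr$B_f >= L / 100)[1L]
    if (is.na(idx)) NULL
    else data.frame(level_pct = L, t_first = tr$t[idx],
                    pop_increase = (tr$population[idx] - P0) / P0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    data.frame(level_pct = numeric(0), t_first = numeric(0),
               pop_increase = numeric(0))
  else out
}
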