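#' Parameters of the deterministic breach-cascade model
#'
#' Configuration of the closed-form counterpart of the stochastic
#' simulation: a city of `M` sequenced neighbourhoods `C_1 .. C_M`
#' sharing `N` residents equally, every resident with tolerance `tau_r`,
#' and a deterministic arrival stream of `x` migrants per neighbourhood
#' per iteration (all arrivals enter; entry is not probabilistic here).
#' When a neighbourhood's migrant-to-resident ratio reaches `tau_r`, all
#' its residents are redistributed equally over the neighbourhoods that
#' follow it in sequence, so breaches cascade in index order. The
#' derived threshold `j = tau_r * N / M` is the migrant load that tips
#' the first neighbourhood.
#'
#' Defaults are the reference configuration: `M = 20`, `N = 5000`,
#' `tau_r = 0.33`, `tau_m = 1`. The migrant tolerance `tau_m` plays no
#' role in the closed forms (migrants are fully tolerant) and is kept
#' only for completeness.
#'
#' @param x Migrants arriving per neighbourhood per iteration (positive).
#' @param M Number of neighbourhoods (at least 2).
#' @param N Total resident count.
#' @param tau_r Resident tolerance level (0 < tau_r <= 1 required for a
#'   positive threshold).
#' @param tau_m Migrant tolerance level (unused by the formulas).
#' @return An object of class `analytical_params`.
#' @examples
#' ap <- analytical_params(x = 1)
#' breach_threshold(ap)  # 0.33 * 5000 / 20 = 82.5
#' @export
analytical_params <- function(x, M = 20L, N = 5000L, tau_r = 0.33, tau_m = 1) {
  p <- list(M = as.integer(M), N = as.integer(N),
            tau_r = as.numeric(tau_r), tau_m = as.numeric(tau_m),
            x = as.numeric(x))
  class(p) <- "analytical_params"
  if (p$M < 2L) stop("'M' must be at least 2")
  if (p$N < 1L) stop("'N' must be positive")
  if (is.na(p$x) || p$x <= 0) stop("'x' must be a positive arrival rate")
  if (is.na(p$tau_r) || p$tau_r <= 0 || p$tau_r > 1)
    stop("'tau_r' must lie in (0, 1] for a positive breach threshold")
  p
}

#' @export
print.analytical_params <- function(x, ...) {
  cat(sprintf(
    "Deterministic breach-cascade parameters: M = %d, N = %d, tau_r = %.3g, x = %.3g (j = %.4g)\n",
    x$M, x$N, x$tau_r, x$x, breach_threshold(x)))
  invisible(x)
}

#' Migrant load that tips the first neighbourhood
#'
#' `j = tau_r * N / M`: the number of migrants in a neighbourhood of
#' `N / M` residents at which the migrant-to-resident ratio reaches the
#' tolerance `tau_r`. Real-valued by construction (the reference
#' configuration gives `j = 82.5`).
#'
#' @param params An [analytical_params()] object.
#' @return The threshold `j`.
#' @export
breach_threshold <- function(params) {
  params$tau_r * params$N / params$M
}

#' Incremental migrants per neighbourhood between successive breaches
#'
#' `I_u`: the additional migrants per neighbourhood needed to tip the
#' `u`-th neighbourhood after the `(u-1)`-th has tipped. `I_1 = j`; for
#' `u >= 2`, `I_u = M j / ((M - u + 1)(M - u + 2))`. The two cases are
#' genuinely piecewise: the general expression evaluated at `u = 1`
#' does not reduce to `j`, but the telescoping sum
#' `sum_{q<=u} I_q = j M / (M - u + 1)` holds exactly under the
#' piecewise definition (see [cumulative_migrants()]). Vectorised over
#' `u`.
#'
#' @param u Breach index (or vector of indices) in `1 .. M - 1`.
#' @param params An [analytical_params()] object.
#' @return Incremental per-neighbourhood migrant load(s).
#' @export
incremental_migrants <- function(u, params) {
  M <- params$M
  if (any(u < 1 | u > M - 1)) stop("'u' must lie in 1 .. M - 1")
  j <- breach_threshold(params)
  ifelse(u == 1, j, M * j / ((M - u + 1) * (M - u + 2)))
}

#' Cumulative migrants per neighbourhood at the u-th breach
#'
#' Total migrant load per (surviving) neighbourhood when the `u`-th
#' neighbourhood tips: `sum_{q=1}^{u} I_q`, which telescopes to the
#' closed form `j M / (M - u + 1)`. Vectorised over `u`.
#'
#' @inheritParams incremental_migrants
#' @return Cumulative per-neighbourhood migrant load(s).
#' @export
cumulative_migrants <- function(u, params) {
  M <- params$M
  if (any(u < 1 | u > M - 1)) stop("'u' must lie in 1 .. M - 1")
  breach_threshold(params) * M / (M - u + 1)
}

#' Time of the u-th breach
#'
#' `T_u = sum_{q=1}^{u} I_q / x`, in iterations. Real-valued: this is
#' the continuous-time point at which the cumulative arrival stream
#' reaches the `u`-th threshold. Vectorised over `u`.
#'
#' @inheritParams incremental_migrants
#' @return Breach time(s) in iterations.
#' @export
breach_time <- function(u, params) {
  cumulative_migrants(u, params) / params$x
}

#' Fraction of residents breached after u breaches
#'
#' `B_u = u / M`: each tipped neighbourhood accounts for the `N / M`
#' residents it originally held. Vectorised over `u`.
#'
#' @param u Breach index (or vector) in `1 .. M`.
#' @param params An [analytical_params()] object.
#' @return Fraction(s) in `(0, 1]`.
#' @export
breach_fraction <- function(u, params) {
  if (any(u < 1 | u > params$M)) stop("'u' must lie in 1 .. M")
  u / params$M
}

#' Mean breach time over the first S breaches
#'
#' `<T> = (T_1 + ... + T_S) / S`, the deterministic counterpart of the
#' mean time to first breach; paired with the breached fraction
#' `B = S / M`.
#'
#' @param S Number of breached neighbourhoods, in `1 .. M - 1`.
#' @param params An [analytical_params()] object.
#' @return Mean breach time in iterations.
#' @export
mean_breach_time <- function(S, params) {
  if (length(S) != 1L || S < 1 || S > params$M - 1)
    stop("'S' must lie in 1 .. M - 1")
  mean(breach_time(seq_len(S), params))
}

#' Population increase at the u-th breach
#'
#' City-wide migrant population at the `u`-th breach as a fraction of
#' the resident population: `M * cumulative_migrants(u) / N`.
#' Independent of the arrival rate `x` (arrivals are uniform and all
#' enter, so the breach thresholds are fixed migrant loads). Vectorised
#' over `u`.
#'
#' @inheritParams incremental_migrants
#' @return Fraction(s) of the initial population.
#' @export
population_increase_at <- function(u, params) {
  params$M * cumulative_migrants(u, params) / params$N
}

#' Full breach schedule
#'
#' The per-breach statistics for `u = 1 .. M - 1`: incremental and
#' cumulative migrant loads, breach times and breached fractions. The
#' last neighbourhood `C_M` never tips in this model (its displaced
#' residents would have nowhere to go), so the breached fraction is
#' capped at `(M - 1) / M`.
#'
#' @param params An [analytical_params()] object.
#' @return An object of class `breach_schedule`: a data frame with
#'   columns `u`, `I_u`, `cumulative`, `T_u`, `B_u` and the parameters
#'   attached as attribute `params`.
#' @export
breach_schedule <- function(params) {
  u <- seq_len(params$M - 1L)
  out <- data.frame(u = u,
                    I_u = incremental_migrants(u, params),
                    cumulative = cumulative_migrants(u, params),
                    T_u = breach_time(u, params),
                    B_u = breach_fraction(u, params))
  attr(out, "params") <- params
  class(out) <- c("breach_schedule", "data.frame")
  out
}

#' Breached fraction as a step function of time
#'
#' `B(t) = u / M` for `T_u <= t < T_{u+1}` and 0 before the first
#' breach, capped at `(M - 1) / M`.
#'
#' @param params An [analytical_params()] object.
#' @param t_max Unused except for validation of intent; the returned
#'   step function is defined for all `t >= 0`.
#' @return A [stats::stepfun()] object.
#' @export
breach_trajectory <- function(params, t_max = NULL) {
  if (!is.null(t_max) && t_max <= 0) stop("'t_max' must be positive")
  sched <- breach_schedule(params)
  stats::stepfun(sched$T_u, c(0, sched$B_u), right = FALSE)
}

#' Discrete-event oracle for the breach cascade
#'
#' Simulates the cascade rules literally, with real-valued migrant
#' mass and integer iterations: each iteration adds `x` migrants to
#' every neighbourhood; neighbourhoods are then swept in sequence and
#' any neighbourhood whose migrant load has reached `tau_r` times its
#' resident count (equality tips) redistributes its residents equally
#' over the neighbourhoods that follow it, possibly cascading within
#' the same iteration. Because time is quantised to whole iterations,
#' the recorded breach iterations bracket the continuous-time
#' [breach_time()] values from above within one iteration, and the
#' migrant-load thresholds at each breach match [cumulative_migrants()]
#' exactly.
#'
#' @param params An [analytical_params()] object.
#' @param t_max Maximum iterations to simulate; defaults to enough to
#'   tip all `M - 1` neighbourhoods.
#' @return A data frame with one row per breach: `u`, `t_breach`
#'   (iteration), `threshold` (migrant load required), `migrants_at_breach`
#'   (load actually present, which can overshoot the threshold when `x`
#'   is large), `B_u`, and column `residents_total` recording the
#'   conserved resident count after each event.
#' @export
analytical_oracle <- function(params, t_max = NULL) {
  M <- params$M
  if (is.null(t_max))
    t_max <- ceiling(breach_time(M - 1L, params)) + 2L
  res <- rep(params$N / M, M)
  mig <- rep(0, M)
  eps <- 1e-9
  events <- list()
  u_count <- 0L
  t <- 0L
  while (u_count < M - 1L && t < t_max) {
    t <- t + 1L
    mig <- mig + params$x
    for (i in seq_len(M - 1L)) {
      if (res[i] > 0 && mig[i] >= params$tau_r * res[i] - eps) {
        u_count <- u_count + 1L
        events[[u_count]] <- data.frame(
          u = u_count, t_breach = t,
          threshold = params$tau_r * res[i],
          migrants_at_breach = mig[i],
          B_u = u_count / M,
          residents_total = sum(res))
        dest <- (i + 1L):M
        res[dest] <- res[dest] + res[i] / length(dest)
        res[i] <- 0
      }
    }
  }
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(u = integer(0), t_breach = integer(0),
                      threshold = numeric(0), migrants_at_breach = numeric(0),
                      B_u = numeric(0), residents_total = numeric(0))
  attr(out, "params") <- params
  out
}

#' @export
print.breach_schedule <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Breach schedule (M = %d, N = %d, tau_r = %.3g, x = %.3g, j = %.4g):\n",
              p$M, p$N, p$tau_r, p$x, breach_threshold(p)))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.breach_schedule <- function(x, ...) {
  p <- attr(x, "params")
  graphics::plot(stats::stepfun(x$T_u, c(0, x$B_u), right = FALSE),
                 do.points = FALSE, xlab = "t (iterations)", ylab = "B",
                 main = sprintf("Breach cascade, x = %.3g", p$x), ...)
  invisible(x)
}
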