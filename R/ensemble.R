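#' Run a seeded ensemble of simulations
#'
#' Runs `n_runs` independent simulations that differ only in seed
#' (`base_seed`, `base_seed + 1`, ...), aligns the trajectories by
#' iteration and aggregates cross-run means and standard deviations of
#' every observable, plus the scalar summaries used for scenario
#' comparison.
#'
#' The scalar `first_breach_time` is the first iteration at which the
#' ensemble-mean ever-breached fraction becomes positive — i.e. the
#' lift-off point of the mean `B_f` curve, equal to the earliest breach
#' across the ensemble. The per-run statistic is also reported as
#' `mean_run_first_breach`.
#'
#' @param params A [model_params()] object (its `seed` field is ignored
#'   in favour of `base_seed`).
#' @param n_runs Ensemble size; 30 by default.
#' @param base_seed Seed of the first run.
#' @return An object of class `tolerance_ensemble`: a list with elements
#'   `params`, `n_runs`, `seeds`, `trajectories` (all runs, long
#'   format), `mean` and `sd` (per-iteration cross-run aggregates) and
#'   `summary` (scalar summaries: `first_breach_time`,
#'   `mean_run_first_breach`, `mean_T_tau`, `mean_final_B_f`,
#'   `peak_mean_B_c`, with standard deviations and the number of runs
#'   entering each).
#' @examples
#' ens <- run_ensemble(model_params(g = 0.05, n_iterations = 40),
#'                     n_runs = 5, base_seed = 1)
#' ens
#' @export
run_ensemble <- function(params, n_runs = 30L, base_seed = params$seed) {
  validate_model_params(params)
  stopifnot(n_runs >= 1L)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    pk <- params
    pk$seed <- seeds[k]
    runs[[k]] <- run_simulation(pk, run_id = k)
  }
  traj <- do.call(rbind, lapply(runs, `[[`, "trajectory"))
  num_cols <- c("population", "migrants", "attempted", "admitted",
                "mean_entry_prob", "B_c", "B_f", "CSI", "growth_rate")
  agg <- function(f) {
    out <- stats::aggregate(traj[num_cols], by = list(t = traj$t), FUN = f,
                            na.rm = TRUE)
    out[order(out$t), ]
  }
  m <- agg(mean)
  s <- agg(stats::sd)
  m[is.nan(as.matrix(m))] <- NA
  per_run <- lapply(runs, summary)
  fb <- vapply(per_run, `[[`, numeric(1), "first_breach_time")
  tt <- vapply(per_run, `[[`, numeric(1), "T_tau")
  bf <- vapply(per_run, `[[`, numeric(1), "final_B_f")
  summ <- list(
    g = params$g,
    n_runs = n_runs,
    first_breach_time = m$t[which(m$B_f > 0)[1L]],
    mean_run_first_breach = mean(fb, na.rm = TRUE),
    sd_run_first_breach = stats::sd(fb, na.rm = TRUE),
    n_runs_breached = sum(!is.na(tt)),
    mean_T_tau = mean(tt, na.rm = TRUE),
    sd_T_tau = stats::sd(tt, na.rm = TRUE),
    mean_final_B_f = mean(bf),
    sd_final_B_f = stats::sd(bf),
    peak_mean_B_c = max(m$B_c)
  )
  structure(
    list(params = params, n_runs = n_runs, seeds = seeds,
         trajectories = traj, mean = m, sd = s,
         run_first_breach = fb, run_T_tau = tt, run_final_B_f = bf,
         summary = summ),
    class = "tolerance_ensemble")
}

#' @export
print.tolerance_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Ensemble of %d runs, g = %.4g (seeds %d..%d)\n",
              x$n_runs, x$params$g, x$seeds[1L], x$seeds[x$n_runs]))
  cat(sprintf("  first breach (mean B_f lift-off) : %s\n",
              format(s$first_breach_time)))
  cat(sprintf("  mean T_tau                       : %.1f (sd %.1f, %d/%d runs breached)\n",
              s$mean_T_tau, s$sd_T_tau, s$n_runs_breached, x$n_runs))
  cat(sprintf("  mean final B_f                   : %.2f%% (sd %.2f%%)\n",
              100 * s$mean_final_B_f, 100 * s$sd_final_B_f))
  cat(sprintf("  peak of mean B_c                 : %.2f%%\n",
              100 * s$peak_mean_B_c))
  invisible(x)
}

#' @export
summary.tolerance_ensemble <- function(object, ...) object$summary

#' @export
as.data.frame.tolerance_ensemble <- function(x, ...) x$trajectories

#' @export
plot.tolerance_ensemble <- function(x, ...) {
  m <- x$mean
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(m$t, m$population, type = "l", xlab = "t", ylab = "mean population",
       main = sprintf("g = %.4g (%d runs)", x$params$g, x$n_runs), ...)
  plot(m$t, 100 * m$B_c, type = "l", xlab = "t", ylab = "mean B_c (%)",
       main = "current breach", ...)
  plot(m$t, 100 * m$B_f, type = "l", xlab = "t", ylab = "mean B_f (%)",
       main = "ever breached", ...)
  plot(m$t, m$CSI, type = "l", ylim = c(0, 1), xlab = "t",
       ylab = "mean CSI", main = "segregation", ...)
  invisible(x)
}

#' Reference scenario registry
#'
#' The standard study conditions: eight stochastic scenarios differing
#' only in the entry rate `g` (0.005, 0.007, 0.01, 0.015, 0.02, 0.03,
#' 0.04, 0.05), each with 20 neighbourhoods, 1000 residents, tolerances
#' 0.25 / 0.75, entry friction 1, a 150% population cap and 200
#' iterations.
#'
#' @param g Entry rates, one scenario per value.
#' @param ... Overrides passed to [model_params()] (applied to every
#'   scenario).
#' @return Named list of [model_params()] objects.
#' @export
default_scenarios <- function(g = c(0.005, 0.007, 0.01, 0.015, 0.02,
                                    0.03, 0.04, 0.05), ...) {
  out <- lapply(g, function(gi) model_params(g = gi, ...))
  names(out) <- paste0("g=", vapply(g, format, character(1)))
  out
}

#' @rdname default_scenarios
#' @param x Arrival rates of the deterministic cascade counterpart, one
#'   [analytical_params()] scenario per value.
#' @export
analytical_scenarios <- function(x = c(0.5, 1, 1.5, 2, 2.5)) {
  out <- lapply(x, analytical_params)
  names(out) <- paste0("x=", vapply(x, format, character(1)))
  out
}

#' Breach-versus-time frontier across entry rates
#'
#' For a set of ensembles at different entry rates, the pairs of mean
#' final ever-breached fraction and mean time to first breach, ordered
#' by `g`. The frontier traces the inverse relationship between how
#' many residents are ever breached and how quickly breaches occur.
#'
#' @param ensembles List of `tolerance_ensemble` objects (at least 2).
#' @return Data frame with columns `g`, `mean_final_B_f`, `mean_T_tau`,
#'   `first_breach_time`.
#' @export
frontier <- function(ensembles) {
  stopifnot(length(ensembles) >= 2L)
  rows <- lapply(ensembles, function(e) {
    s <- e$summary
    data.frame(g = s$g, mean_final_B_f = s$mean_final_B_f,
               mean_T_tau = s$mean_T_tau,
               first_breach_time = s$first_breach_time)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$g), ]
  rownames(out) <- NULL
  out
}

#' Write ensemble and cascade results to disk
#'
#' Writes tidy CSVs (per-run trajectories, per-iteration aggregates,
#' the frontier, analytical schedules) and a JSON manifest recording
#' parameters, seeds and the package version, sufficient to re-run
#' every scenario exactly.
#'
#' @param ensembles List of `tolerance_ensemble` objects (may be empty).
#' @param out_dir Output directory (created if needed).
#' @param schedules Optional list of [breach_schedule()] objects.
#' @return Invisibly, the paths of the files written.
#' @export
write_report <- function(ensembles, out_dir, schedules = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (length(ensembles)) {
    wr(do.call(rbind, lapply(ensembles, `[[`, "trajectories")),
       "trajectories.csv")
    aggs <- do.call(rbind, lapply(ensembles, function(e) {
      long <- function(df, stat) {
        cbind(g = e$params$g, stat = stat, df)
      }
      rbind(long(e$mean, "mean"), long(e$sd, "sd"))
    }))
    wr(aggs, "aggregates.csv")
    if (length(ensembles) >= 2L) wr(frontier(ensembles), "frontier.csv")
  }
  if (length(schedules)) {
    sched <- do.call(rbind, lapply(schedules, function(s) {
      cbind(x = attr(s, "params")$x, as.data.frame(s))
    }))
    wr(sched, "analytical_schedules.csv")
  }
  manifest <- list(
    package = "migtol",
    version = as.character(utils::packageVersion("migtol")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scenarios = lapply(ensembles, function(e)
      list(params = unclass(e$params), n_runs = e$n_runs, seeds = e$seeds)),
    analytical = lapply(schedules, function(s) unclass(attr(s, "params"))),
    files = basename(paths)
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mpath))
}

#' Parameter sweep over scenario grids
#'
#' Robustness helper: runs an ensemble for every row of a parameter
#' grid applied on top of a base scenario and collects the scalar
#' summaries.
#'
#' @param base_params A [model_params()] object.
#' @param grid Data frame whose columns name [model_params()] fields
#'   (e.g. `g`, `tau_res`, `beta_in`, `max_pop_factor`); one ensemble
#'   per row.
#' @param n_runs Ensemble size per grid point.
#' @param base_seed Seed of the first run of the first grid point;
#'   successive grid points use disjoint seed blocks.
#' @return Data frame: the grid columns plus `first_breach_time`,
#'   `mean_T_tau`, `mean_final_B_f`, `peak_mean_B_c`.
#' @export
run_sweep <- function(base_params, grid, n_runs = 30L,
                      base_seed = base_params$seed) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p <- base_params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][r]
    p <- validate_model_params(p)
    e <- run_ensemble(p, n_runs = n_runs,
                      base_seed = base_seed + (r - 1L) * n_runs)
    s <- e$summary
    cbind(grid[r, , drop = FALSE],
          data.frame(first_breach_time = s$first_breach_time,
                     mean_T_tau = s$mean_T_tau,
                     mean_final_B_f = s$mean_final_B_f,
                     peak_mean_B_c = s$peak_mean_B_c))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
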