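test_that("attempted entry count follows the capped rate rule with half-up rounding", {
  p <- model_params(g = 0.005)
  expect_identical(attempted_migrants(1000, 1000, p), 5L)
  expect_identical(attempted_migrants(1500, 1000, p), 0L)  # at the cap
  expect_identical(attempted_migrants(1100, 1000, p), 6L)  # 5.5 rounds up
  p7 <- model_params(g = 0.007)
  expect_identical(attempted_migrants(1010, 1000, p7), 7L) # round(7.07)
})

test_that("entry probability has the exponential closed form", {
  expect_equal(entry_probability(1.0, 1.0), exp(-1))
  expect_equal(entry_probability(0.0, 5), 1.0)
  expect_equal(entry_probability(0.5, 0.0), 1.0)  # frictionless limit
  expect_error(entry_probability(0.5, -1), "beta_in")
  expect_error(entry_probability(1.5, 1), "resident_fraction")
})

test_that("entry phase admits all attempts when frictionless and none under huge friction", {
  p0 <- model_params(g = 0.1, beta_in = 0)
  st <- init_city(p0); st$t <- 1L
  set.seed(1)
  es <- entry_phase(st, p0)
  expect_identical(es$admitted, es$attempted)
  expect_identical(es$attempted, 100L)
  expect_equal(es$entry_probabilities, rep(1, 100))

  pinf <- model_params(g = 0.1, beta_in = 1000)
  st <- init_city(pinf); st$t <- 1L
  set.seed(1)
  es <- entry_phase(st, pinf)
  expect_identical(es$admitted, 0L)
  expect_identical(sum(st$mig_count), 0L)
})

test_that("admission rate into an all-resident city matches the binomial e^-1 law", {
  # with cells large enough that admissions barely dent the resident
  # fraction, each attempt succeeds with p close to e^-1; check the
  # Monte-Carlo rate within 4 binomial SEs of that law
  p <- model_params(g = 0.01, M = 10, n_residents = 100000, beta_in = 1)
  st <- init_city(p); st$t <- 1L
  set.seed(42)
  es <- entry_phase(st, p)
  rate <- es$admitted / es$attempted
  p_true <- exp(-1)
  se <- sqrt(p_true * (1 - p_true) / es$attempted)
  expect_identical(es$attempted, 1000L)
  expect_lt(abs(rate - p_true), 4 * se + 0.01)
})

test_that("a single movement attempt follows the relocation rule and records breaches", {
  p <- model_params(g = 0.01, M = 4, n_residents = 8, tau_res = 0.25)
  # resident 1 in cell 1 with no migrants: satisfied, no move, no breach
  st <- make_state(c(2, 2, 2, 2), c(0, 0, 0, 0)); st$t <- 3L
  expect_false(attempt_move(st, 1, p))
  expect_false(any(st$ever_breached))

  # breached resident with all-resident candidates: moves and is marked
  st <- make_state(c(2, 2, 2, 2), c(3, 0, 0, 0)); st$t <- 3L
  set.seed(1)
  expect_true(attempt_move(st, 1, p))
  expect_true(st$ever_breached[1])
  expect_identical(st$first_breach[1], 3L)
  expect_identical(st$res_count[1], 1L)

  # M = 2 and the only other cell also breaches: stays, still marked
  p2 <- model_params(g = 0.01, M = 2, n_residents = 4, tau_res = 0.25)
  st <- make_state(c(2, 2), c(3, 3)); st$t <- 7L
  expect_false(attempt_move(st, 1, p2))
  expect_true(st$ever_breached[1])
  expect_identical(st$first_breach[1], 7L)
  expect_identical(st$res_count, c(2L, 2L))
})

test_that("movement phase is draw-for-draw equivalent to repeated attempt_move", {
  p <- small_params(seed = 11)
  mk <- function(use_phase) {
    set.seed(31)
    st <- init_city(p)
    for (t in 1:15) {
      st$t <- st$t + 1L
      entry_phase(st, p)
      if (use_phase) {
        movement_phase(st, p)
      } else {
        P <- city_population(st)
        for (a in sample.int(P, P, replace = TRUE)) attempt_move(st, a, p)
      }
    }
    st
  }
  a <- mk(TRUE); b <- mk(FALSE)
  for (f in c("res_cell", "mig_cell", "res_count", "mig_count",
              "ever_breached", "first_breach"))
    expect_identical(a[[f]], b[[f]], info = f)
})

test_that("no one moves when everyone is satisfied", {
  p <- model_params(g = 0, n_iterations = 5)
  sim <- run_simulation(p)
  expect_identical(sim$trajectory$population, rep(1000L, 6))
  expect_equal(sim$trajectory$B_f, rep(0, 6))

  ptol <- small_params(tau_res = 1, tau_mig = 1, seed = 2)
  st <- init_city(ptol); st$t <- 1L
  set.seed(5)
  entry_phase(st, ptol)
  before <- st$res_cell
  expect_identical(movement_phase(st, ptol), 0L)
  expect_identical(st$res_cell, before)
})

test_that("runs are deterministic under a fixed seed and leave the global RNG intact", {
  p <- small_params(seed = 123)
  set.seed(777)
  u_before <- runif(1)
  set.seed(777)
  s1 <- run_simulation(p)
  u_after <- runif(1)
  s2 <- run_simulation(p)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$breach_table, s2$breach_table)
  expect_identical(u_before, u_after)  # seed restored around the run

  s3 <- run_simulation(small_params(seed = 124))
  expect_false(identical(s1$trajectory, s3$trajectory))
})

test_that("conservation, monotonicity and the population cap hold along a run", {
  p <- model_params(g = 0.05, seed = 9)
  sim <- run_simulation(p)
  tr <- sim$trajectory
  # residents conserved
  expect_identical(sum(sim$state$res_count), p$n_residents)
  expect_identical(length(sim$state$res_cell), p$n_residents)
  # population bookkeeping: P(t) - P(t-1) = admitted
  expect_identical(diff(tr$population), as.integer(tr$admitted[-1]))
  # B_f nondecreasing
  expect_true(all(diff(tr$B_f) >= 0))
  # cap: no attempts once P(t-1) is at the cap; overshoot only by one
  # iteration's admissions
  over <- which(tr$population[-nrow(tr)] >= 1500)
  expect_true(all(tr$attempted[over + 1] == 0))
  expect_gte(max(tr$population), 1500L)  # g = 0.05 reaches the cap
  expect_identical(tail(tr$attempted, 1), 0L)
})

test_that("brute-force recounts match the incremental bookkeeping every iteration", {
  p <- small_params(seed = 21)
  set.seed(8)
  st <- init_city(p)
  for (t in 1:20) {
    st$t <- st$t + 1L
    entry_phase(st, p)
    movement_phase(st, p)
    # counts from raw agent positions
    expect_identical(st$res_count, tabulate(st$res_cell, st$M))
    expect_identical(st$mig_count, tabulate(st$mig_cell, st$M))
    # current breach fraction from first principles
    frac <- vapply(seq_len(st$M), function(i)
      cell_composition(st, i)[["migrant_frac"]], numeric(1))
    breached_cells <- which(!is_satisfied("resident", frac, p) )
    expect_equal(current_breach_fraction(st, p),
                 sum(st$res_count[breached_cells]) / st$n_res)
    # ever-breached flags agree with the recorded first-breach times
    expect_identical(st$ever_breached, !is.na(st$first_breach))
    expect_true(all(st$first_breach <= st$t, na.rm = TRUE))
  }
})

test_that("mean entry probability trends upwards as breaches concentrate migrants", {
  ens <- run_ensemble(model_params(g = 0.03), n_runs = 5, base_seed = 400)
  m <- ens$mean
  pre_cap <- which(!is.na(m$mean_entry_prob) & m$attempted > 0)
  rho <- cor(m$t[pre_cap], m$mean_entry_prob[pre_cap], method = "spearman")
  expect_gt(rho, 0)
})
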