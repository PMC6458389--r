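test_that("breach fractions follow their defining ratios", {
  p <- model_params(g = 0.01, M = 4, n_residents = 1000, tau_res = 0.25)
  st <- make_state(c(250, 250, 250, 250), c(0, 0, 0, 0))
  expect_equal(current_breach_fraction(st, p), 0)
  expect_equal(ever_breached_fraction(st), 0)

  # 20 residents share a cell that is half migrant: only they are breached
  st <- make_state(c(20, 490, 490, 0), c(20, 0, 0, 0))
  expect_equal(current_breach_fraction(st, p), 20 / 1000)

  # boundary: exactly tau_res is not a breach
  st <- make_state(c(3, 997, 0, 0), c(1, 0, 0, 0))
  expect_equal(current_breach_fraction(st, p), 0)

  st <- make_state(c(1000, 0, 0, 0), c(1000, 0, 0, 0))
  expect_equal(current_breach_fraction(st, p), 1.0)

  st$ever_breached[1:53] <- TRUE
  expect_equal(ever_breached_fraction(st), 0.053)
})

test_that("mean time to first breach averages the breached and rejects the empty case", {
  expect_equal(mean_time_to_first_breach(c(10, 20)), 15)
  expect_equal(mean_time_to_first_breach(
    data.frame(agent_id = 1L, first_breach_iteration = 5)), 5)
  expect_error(mean_time_to_first_breach(numeric(0)), "undefined")
  sim <- run_simulation(model_params(g = 0, n_iterations = 3))
  expect_error(mean_time_to_first_breach(sim), "undefined")
})

test_that("CSI matches hand evaluations and its bounds", {
  # fully segregated: every non-empty cell single-type
  st <- make_state(c(10, 0, 5), c(0, 7, 0))
  expect_equal(csi(st), 1.0)

  # proportional mixing: every cell holds equal shares of both totals
  st <- make_state(c(10, 10), c(4, 4))
  expect_equal(csi(st), 0.0)

  # hand evaluation: residents (3,1) of 4, migrants (1,1) of 2
  st <- make_state(c(3, 1), c(1, 1))
  expect_equal(csi(st), (abs(3/4 - 1/2)/(3/4 + 1/2) + abs(1/4 - 1/2)/(1/4 + 1/2)) / 2)
  expect_equal(csi(st), 0.2666667, tolerance = 1e-6)

  # zero-migrant convention: defined and equal to 1 from the start
  expect_equal(csi(init_city(model_params(g = 0.01))), 1.0)
  expect_error(csi(make_state(c(0, 0), c(0, 0))), "empty")

  # bounds on random compositions
  set.seed(3)
  for (k in 1:25) {
    st <- make_state(rpois(6, 20), rpois(6, 5))
    if (sum(st$res_count) + sum(st$mig_count) == 0) next
    v <- csi(st)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("periodic growth rate reproduces population ratios and window means", {
  tr <- data.frame(t = 0:3, population = c(1000, 1005, 1005, 1206),
                   admitted = c(NA, 5, 0, 201), B_f = 0)
  r <- periodic_growth_rate(tr)
  expect_equal(unname(r), c(0.005, 0, 0.2))
  expect_equal(periodic_growth_rate(tr, window = c(1, 2)), 0.0025)
  # pre-cap window ends at the last iteration with admissions
  expect_equal(periodic_growth_rate(tr, window = "precap"),
               mean(c(0.005, 0, 0.2)))
  tr2 <- tr; tr2$admitted <- c(NA, 5, 5, 0); tr2$population <- c(1000, 1005, 1010, 1010)
  expect_equal(periodic_growth_rate(tr2, window = "precap"),
               mean(c(0.005, 5 / 1005)))
})

test_that("percent-level breach tables are monotone and anchored correctly", {
  tr <- data.frame(t = 0:5,
                   population = c(1000, 1100, 1200, 1300, 1400, 1500),
                   B_f = c(0, 0, 0.004, 0.012, 0.012, 0.051))
  tab <- time_per_breach_percent(tr)
  expect_equal(tab$level_pct, 0:5)
  expect_equal(tab$t_first[tab$level_pct == 0], 2)  # first t with B_f > 0
  expect_equal(tab$t_first[tab$level_pct == 1], 3)
  expect_equal(tab$t_first[tab$level_pct == 5], 5)
  expect_true(all(diff(tab$t_first) >= 0))
  # unattained levels are absent
  expect_false(6 %in% time_per_breach_percent(tr, levels = 0:10)$level_pct)

  curve <- breach_vs_population_curve(tr)
  expect_equal(curve$pop_increase[curve$level_pct == 0], 0)  # at t = 0
  expect_equal(curve$pop_increase[curve$level_pct == 1], 0.3)
  expect_equal(curve$pop_increase[curve$level_pct == 5], 0.5)
})

test_that("current breach never exceeds ever-breached under census marking", {
  p <- model_params(g = 0.05, seed = 31, census_breach_marking = TRUE,
                    n_iterations = 120)
  tr <- run_simulation(p)$trajectory
  expect_true(all(tr$B_c <= tr$B_f + 1e-12))
  expect_true(all(tr$B_f >= 0 & tr$B_f <= 1))
  expect_true(all(tr$CSI >= 0 & tr$CSI <= 1))
})
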