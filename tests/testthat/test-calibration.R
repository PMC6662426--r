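toy_series <- function(ac, lc, ages = seq_along(ac)) {
  carbon_density_series(ages, AC = ac, BC = ac * 0.4, LC = lc)
}

test_that("the objective is zero iff simulation equals observation", {
  obs <- toy_series(c(1, 2, 3), c(0.1, 0.2, 0.3))
  spec <- objective_spec(obs)
  expect_equal(objective_f(obs, spec), 0)
  sim <- obs; sim$AC[2] <- 2.2
  expect_gt(objective_f(sim, spec), 0)
})

test_that("hand-computed objective values are reproduced exactly", {
  # n = 2, all four relative errors 0.1, weights (25, 5):
  # (0.01 + 0.01 + 25*0.01 + 5*0.01) / (2 + 30) = 0.01
  obs <- toy_series(c(1, 2), c(0.1, 0.2))
  sim <- toy_series(c(1.1, 2.2), c(0.11, 0.22))
  expect_equal(objective_f(sim, objective_spec(obs, 25, 5)), 0.01,
               tolerance = 1e-14)
  # n = 1: only the weighted final-year terms remain
  obs1 <- toy_series(1, 0.1)
  sim1 <- toy_series(1.1, 0.11)
  expect_equal(objective_f(sim1, objective_spec(obs1, 25, 5)), 0.01,
               tolerance = 1e-14)
})

test_that("the objective is scale-invariant and error-monotone", {
  set.seed(12)
  obs <- toy_series(runif(6, 0.5, 3), runif(6, 0.05, 0.3))
  sim <- toy_series(obs$AC * runif(6, 0.9, 1.1), obs$LC * runif(6, 0.9, 1.1))
  spec <- objective_spec(obs)
  f0 <- objective_f(sim, spec)
  for (k in c(0.1, 3, 42)) {
    obs_k <- toy_series(obs$AC * k, obs$LC * k)
    sim_k <- toy_series(sim$AC * k, sim$LC * k)
    expect_equal(objective_f(sim_k, objective_spec(obs_k)), f0,
                 tolerance = 1e-12)
  }
  worse <- sim; worse$AC[3] <- obs$AC[3] * 1.5
  expect_gt(objective_f(worse, spec), f0)
  # zero observations are rejected (relative errors undefined)
  bad <- obs; bad$LC[1] <- 0
  expect_error(objective_spec(bad), "positive")
})

test_that("DIRECT solves the standard benchmarks inside budget", {
  sphere <- function(x) sum(x^2)
  r <- direct_optimize(sphere, c(-5, -5), c(5, 5), budget = 500)
  expect_lte(r$value, 1e-6)
  expect_lte(r$evaluations, 500)
  shifted <- function(x) sum((x - c(1.3, -2.1))^2)
  rs <- direct_optimize(shifted, c(-5, -5), c(5, 5), budget = 500)
  expect_lte(rs$value, 1e-6)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  rr <- direct_optimize(rosen, c(-2, -2), c(2, 2), budget = 5000)
  expect_lte(rr$value, 1e-3)
})

test_that("DIRECT stays inside the box with a nonincreasing best value", {
  seen <- list()
  fn <- function(x) { seen[[length(seen) + 1]] <<- x; sum(sin(3 * x)) + sum(x^2) / 10 }
  r <- direct_optimize(fn, c(-4, -1), c(2, 3), budget = 400)
  pts <- do.call(rbind, seen)
  expect_true(all(pts[, 1] >= -4 & pts[, 1] <= 2))
  expect_true(all(pts[, 2] >= -1 & pts[, 2] <= 3))
  expect_true(all(diff(r$trace) <= 0))
  # constant objective: center of the box, no crash
  rc <- direct_optimize(function(x) 7, c(0, 0), c(1, 1), budget = 50)
  expect_equal(rc$value, 7)
  expect_equal(rc$par, c(0.5, 0.5))
})

test_that("the evolutionary cross-check is seeded and competent", {
  sphere <- function(x) sum(x^2)
  r1 <- ea_optimize(sphere, c(-5, -5), c(5, 5), budget = 2000, seed = 1)
  r2 <- ea_optimize(sphere, c(-5, -5), c(5, 5), budget = 2000, seed = 1)
  expect_identical(r1$trace, r2$trace)
  expect_lte(r1$value, 1e-4)
  expect_gte(r1$value, 0)           # never better than the true minimum
  expect_true(all(diff(r1$trace) <= 0))
})

test_that("phase i returns the defaults untouched", {
  p <- ecophys_params()
  cal <- calibrate_phase("i", params_default = p)
  expect_identical(cal$params, p)
  expect_equal(cal$evaluations, 0L)
})

test_that("phase calibration pins the coarse-root ratio to the data", {
  f <- test_forcing()
  init <- test_init()
  obs <- generate_observations(ecophys_params(), test_site(), f, 5,
                               init = init)
  cal <- calibrate_phase("ii", obs, ecophys_params(), test_site(), f,
                         budget = 60, polish = FALSE, init = init)
  expect_equal(cal$params$crc_sc, bc_ac_mean_ratio(obs))
  expect_equal(cal$years_used, 1:5)
  # phase ii needs observations through age 5
  expect_error(calibrate_phase("ii", obs[1:3, ], ecophys_params(),
                               test_site(), f), "ages")
})
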