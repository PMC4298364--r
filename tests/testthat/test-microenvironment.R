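test_that("mean-fitness curve has the stated boundary behaviour", {
  env <- env_spec()
  # F(0) = 1 - 0.7/5201, rounds to 1.00
  expect_equal(mean_fitness_curve(0, env), 1 - 0.7 / 5201)
  expect_equal(round(mean_fitness_curve(0, env), 2), 1.00)
  # late-life limit is f_min
  expect_equal(mean_fitness_curve(1e7, env), 0.3)
  expect_equal(mean_fitness_curve(4420, env), 0.304, tolerance = 1e-3)
  # strictly decreasing
  F <- mean_fitness_curve(seq(0, 6000, by = 10), env)
  expect_true(all(diff(F) < 0))
  expect_error(env_spec(f_min = 1.2), "f_max > f_min")
  expect_error(env_spec(scale = -1), "positive")
})

test_that("weekly drop is the analytic derivative and telescopes", {
  env <- env_spec()
  expect_equal(weekly_fitness_drop(0, env), 4.2e-7, tolerance = 0.02)
  # sum of weekly drops ~ total decline F(0) - F(4420) (quadrature oracle)
  total <- sum(weekly_fitness_drop(0:4419, env))
  expect_equal(total, mean_fitness_curve(0, env) - mean_fitness_curve(4420, env),
               tolerance = 0.01)
  expect_true(all(weekly_fitness_drop(0:4420, env) >= 0))
  flat <- env_spec(f_max = 1, f_min = 1 - 1e-12)
  expect_equal(weekly_fitness_drop(c(0, 100, 4000), flat), rep(0, 3),
               tolerance = 1e-11)
})

test_that("distributed draws follow the sign-mixture with spread dF/2", {
  env <- env_spec(f_max = 1, f_min = 1 - 1e-15)
  expect_equal(sample_env_effects(0, 10, env), rep(0, 10), tolerance = 1e-12)

  env0 <- env_spec(positive_tail_fraction = 0)
  set.seed(5)
  x <- sample_env_effects(2500, 1e4, env0)
  expect_true(all(x <= 0))

  env5 <- env_spec(positive_tail_fraction = 0.5)
  t <- 2760 # near the logistic midpoint, where the drop is largest
  target_sd <- weekly_fitness_drop(t, env5) / 2
  set.seed(6)
  y <- sample_env_effects(t, 1e5, env5)
  expect_lt(abs(sd(y) - target_sd), 3 * target_sd / sqrt(2 * 1e5))
  expect_lt(abs(mean(y)), 3 * target_sd / sqrt(1e5))

  # variance interpretation: magnitude scale sqrt(dF/2)
  envv <- env_spec(positive_tail_fraction = 0.5, spread = "variance")
  set.seed(7)
  z <- sample_env_effects(t, 1e5, envv)
  expect_lt(abs(sd(z) - sqrt(target_sd)), 3 * sqrt(target_sd) / sqrt(2 * 1e5))
})

test_that("symmetric environment tracks the mean-fitness curve in simulation", {
  # mutations off, env tail 50%: no selection differential beyond the
  # symmetric walk, so pool mean fitness should follow F(A)
  cfg <- preset_config("composite",
                       schedules = hsc_schedules(adult_size = 500),
                       lifespan_weeks = 4420)
  cfg$dfe$sigma <- 0
  ends <- replicate_stat(cfg, seeds = 1:5,
                         function(s) glance(s)$end_fitness)
  expect_gte(mean(ends), 0.25)
  expect_lte(mean(ends), 0.35)
})

test_that("transient environmental draws do not accumulate across weeks", {
  # steep custom curve so the weekly spread is non-negligible from week 0
  mk <- function(persistent) {
    sim_config(
      lifespan_weeks = 50, initial_cells = 2000,
      schedules = flat_division_schedules(0, adult_size = 4000,
                                          initial_cells = 2000),
      dfe = dfe_spec(sigma = 0, tier3_rate_per_division = 0),
      env = env_spec(enabled = TRUE, scale = 1, rate = 0.1,
                     persistent = persistent),
      seed = 12)
  }
  sd_p <- sd(run_simulation(mk(TRUE))$final_pool$fitness)
  sd_t <- sd(run_simulation(mk(FALSE))$final_pool$fitness)
  env <- env_spec(scale = 1, rate = 0.1)
  one_week_sd <- weekly_fitness_drop(50, env) / 2
  # persistent: a random walk, spread grows ~ sqrt(weeks); transient: only
  # the current week's draw remains
  expect_gt(sd_p, 3 * sd_t)
  expect_lt(abs(sd_t - one_week_sd), 0.2 * one_week_sd)
})

test_that("environment draws come from an independent RNG stream", {
  # a run with an (effectively) zero-magnitude environment consumes only the
  # environment stream, so division/DFE-driven outputs match the disabled run
  base <- tiny_config(dfe = dfe_spec(sigma = 1e-3, tier3_rate_per_division = 0.05),
                      seed = 42)
  off <- base
  off$env <- env_spec(enabled = FALSE)
  on_zero <- base
  on_zero$env <- env_spec(enabled = TRUE, f_max = 1, f_min = 1 - 1e-12)
  a <- run_simulation(off)$trajectory
  b <- run_simulation(on_zero)$trajectory
  expect_identical(a$pool_size, b$pool_size)
  expect_identical(a$mean_tier3, b$mean_tier3)
  expect_identical(a$n_clones, b$n_clones)
  expect_equal(a$mean_fitness, b$mean_fitness, tolerance = 1e-8)
})
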