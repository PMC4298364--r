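test_that("pool initialization matches the configuration", {
  cfg <- sim_config(schedules = hsc_schedules())
  pool <- initialize_pool(cfg)
  expect_identical(length(pool$fitness), 300L)
  expect_true(all(pool$fitness == 1))
  expect_true(all(pool$tier3 == 0))
  expect_identical(sort(unique(pool$clone)), 1:300)
  expect_identical(pool$week, 0L)

  small <- tiny_config(initial_cells = 10,
                       schedules = hsc_schedules(initial_cells = 10,
                                                 adult_size = 100))
  expect_identical(length(initialize_pool(small)$fitness), 10L)

  single <- tiny_config(initial_clones = "single")
  expect_identical(unique(initialize_pool(single)$clone), 1L)

  p1 <- initialize_pool(cfg); p2 <- initialize_pool(cfg)
  expect_identical(p1$fitness, p2$fitness)
  expect_identical(p1$clone, p2$clone)
})

test_that("division respects the weekly probability and inheritance", {
  # p = 0: nothing happens
  cfg0 <- tiny_config(schedules = flat_division_schedules(0, 300, 50))
  pool <- initialize_pool(cfg0)
  expect_identical(divide_cells(pool, cfg0)$fitness, pool$fitness)

  # p = 1, sigma = 0, mu0 = 0: the pool doubles, all state inherited
  cfg1 <- tiny_config(
    schedules = flat_division_schedules(1, 300, 50),
    dfe = dfe_spec(sigma = 0, tier3_rate_per_division = 0))
  pool <- initialize_pool(cfg1)
  out <- divide_cells(pool, cfg1)
  expect_identical(length(out$fitness), 100L)
  expect_true(all(out$fitness == 1))
  expect_true(all(out$tier3 == 0))

  # p = 0.5 on 10^4 cells: dividing fraction within 3 binomial SE
  n <- 1e4
  cfg5 <- sim_config(
    lifespan_weeks = 10, initial_cells = n,
    schedules = flat_division_schedules(0.5, 3 * n, n),
    dfe = dfe_spec(sigma = 0, tier3_rate_per_division = 0), seed = 3)
  pool <- initialize_pool(cfg5)
  grown <- length(divide_cells(pool, cfg5)$fitness)
  frac <- (grown - n) / n
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("clone assignment follows the founder-divergence threshold", {
  theta <- 0.05
  # no deviation: same clone
  r <- assign_clones(fitness = 1, clone = 1L, founder_fitness = 1,
                     theta = theta, next_clone = 2L)
  expect_identical(r$clone, 1L)
  # deviation 2 theta: new clone issued
  r <- assign_clones(fitness = 1 + 2 * theta, clone = 1L, founder_fitness = 1,
                     theta = theta, next_clone = 2L)
  expect_identical(r$clone, 2L)
  expect_equal(unname(r$founder_fitness), 1 + 2 * theta)

  # scripted drift: +0.6 theta per division relative to the current founder
  # crosses the threshold on every second division
  founder <- c(1, rep(NA, 20)); next_id <- 2L; clone <- 1L; fit <- 1
  new_flags <- logical(8)
  for (i in 1:8) {
    # fitness moves +0.6 theta at each division
    fit <- 1 + 0.6 * theta * i
    r <- assign_clones(fit, clone, founder, theta, next_id)
    new_flags[i] <- r$clone != clone
    if (new_flags[i]) {
      founder[as.integer(names(r$founder_fitness))] <- r$founder_fitness
      next_id <- r$next_clone
    }
    clone <- r$clone
  }
  expect_identical(new_flags, rep(c(FALSE, TRUE), 4))
  expect_error(assign_clones(1, 1L, 1, theta = 0, next_clone = 2L), "> 0")
})

test_that("competition removes exactly the overflow, weighted by fitness", {
  cfg <- tiny_config(schedules = flat_division_schedules(0, adult_size = 100,
                                                         initial_cells = 50))
  pool <- initialize_pool(cfg)
  expect_identical(length(apply_competition(pool, cfg)$fitness), 50L)

  # helper: an over-capacity pool built by duplicating cells by hand
  oversize_pool <- function(cfg, fitness, clone) {
    p <- initialize_pool(cfg)
    p$fitness <- fitness
    p$tier3 <- rep(0, length(fitness))
    p$clone <- clone
    p$env_dev <- rep(0, length(fitness))
    p
  }

  # equal fitness, n = 2N: every cell survives with probability ~ 1/2
  cfg2 <- sim_config(lifespan_weeks = 1, initial_cells = 100,
                     schedules = flat_division_schedules(0, adult_size = 100,
                                                         initial_cells = 100),
                     seed = 1)
  n_surv_first <- replicate(200, {
    cfg2$seed <- sample.int(1e6, 1)
    p <- oversize_pool(cfg2, rep(1, 200),
                       c(1L, rep(2L, 199))) # track cell 1 via its clone id
    out <- apply_competition(p, cfg2)
    expect_identical(length(out$fitness), 100L)
    1L %in% out$clone
  })
  bt <- binom.test(sum(n_surv_first), 200, p = 0.5)
  expect_gt(bt$p.value, 1e-4)

  # two cells, capacity one, fitness (1, eps): the fit cell nearly always wins
  eps <- 0.02
  cfg3 <- sim_config(lifespan_weeks = 1, initial_cells = 1,
                     schedules = flat_division_schedules(0, adult_size = 1,
                                                         initial_cells = 1),
                     seed = 1)
  wins <- replicate(400, {
    cfg3$seed <- sample.int(1e6, 1)
    p <- oversize_pool(cfg3, c(1, eps), c(1L, 2L))
    apply_competition(p, cfg3)$clone == 1L
  })
  bt2 <- binom.test(sum(wins), 400, p = 1 / (1 + eps))
  expect_gt(bt2$p.value, 1e-4)
})

test_that("weekly step composes the mechanisms in order", {
  # neutral everything: fitness stays exactly 1
  cfg <- tiny_config(dfe = dfe_spec(sigma = 0, tier3_rate_per_division = 0))
  pool <- initialize_pool(cfg)
  for (i in 1:20) pool <- step_week(pool, cfg)
  expect_true(all(pool$fitness == 1))
  expect_identical(pool$week, 20L)

  # env on, no division: a single step drops mean fitness by ~ dF(0)
  cfgE <- sim_config(
    lifespan_weeks = 4, initial_cells = 5000,
    schedules = flat_division_schedules(0, adult_size = 20000,
                                        initial_cells = 5000),
    dfe = dfe_spec(sigma = 0, tier3_rate_per_division = 0),
    env = env_spec(enabled = TRUE), seed = 9)
  pool <- initialize_pool(cfgE)
  pool <- step_week(pool, cfgE)
  dF0 <- weekly_fitness_drop(0, cfgE$env)
  expect_equal(mean(pool$fitness), 1 - dF0,
               tolerance = 3 * (dF0 / 2) / sqrt(5000) / (1 - dF0) + 1e-12)

  # capacity contract after any step
  cfgC <- tiny_config(lifespan_weeks = 60)
  pool <- initialize_pool(cfgC)
  for (t in 1:60) {
    pool <- step_week(pool, cfgC)
    expect_lte(length(pool$fitness), carrying_capacity(pool$week, cfgC$schedules))
  }
})

test_that("full runs are reproducible and trajectory-complete", {
  cfg <- tiny_config(lifespan_weeks = 150, seed = 21)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(nrow(a$trajectory), 151L)
  expect_identical(a$trajectory$week[151], 150L)

  # zero lifespan: only the initial state
  cfg0 <- tiny_config(lifespan_weeks = 0)
  tr <- run_simulation(cfg0)$trajectory
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$pool_size, 50)

  # different seed diverges
  cfg2 <- tiny_config(lifespan_weeks = 150, seed = 22)
  expect_false(identical(run_simulation(cfg2)$trajectory, a$trajectory))
})

test_that("neutral tier-3 accrual matches the analytic expectation", {
  # sigma = 0, env off: population-mean tier3 at T should equal
  # mu0 * sum_t m(t) * 2 d(t) / (1 + d(t)) -- independent quadrature oracle
  sch <- hsc_schedules(initial_cells = 100, adult_size = 500)
  mu0 <- 0.05; fold <- 3; L <- 520
  cfg <- sim_config(
    lifespan_weeks = L, initial_cells = 100, schedules = sch,
    dfe = dfe_spec(sigma = 0, tier3_rate_per_division = mu0,
                   rate_fold_increase = fold),
    seed = 1)
  t <- 0:(L - 1)
  d <- division_probability(t, sch)
  m <- 1 + (fold - 1) * t / L
  expected <- sum(mu0 * m * 2 * d / (1 + d))
  ends <- replicate_stat(cfg, seeds = 1:8, function(s) glance(s)$end_tier3)
  se <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - expected), 3 * se + 0.02 * expected)
})

test_that("wide negative-tail DFEs purge dividing lineages (purifying selection)", {
  mk <- function(sigma) {
    sim_config(
      lifespan_weeks = 1040, initial_cells = 100,
      schedules = hsc_schedules(initial_cells = 100, adult_size = 500),
      dfe = dfe_spec(sigma = sigma, positive_tail_fraction = 0,
                     tier3_rate_per_division = 0.1),
      seed = 1)
  }
  # a heavily purged pool can go extinct before the end of the window;
  # compare the last observed population-mean burden in that case
  last_tier3 <- function(s) {
    v <- s$trajectory$mean_tier3
    v <- v[!is.na(v)]
    v[length(v)]
  }
  wide <- mean(replicate_stat(mk(5e-1), 1:4, last_tier3))
  narrow <- mean(replicate_stat(mk(5e-6), 1:4, last_tier3))
  expect_lt(wide, narrow)
})

test_that("asymmetric division keeps the mother and adds one daughter", {
  cfg <- tiny_config(
    schedules = flat_division_schedules(1, 300, 50),
    dfe = dfe_spec(sigma = 0, tier3_rate_per_division = 0),
    division_mode = "asymmetric")
  pool <- initialize_pool(cfg)
  out <- divide_cells(pool, cfg)
  expect_identical(length(out$fitness), 100L)
  expect_identical(out$clone[1:50], pool$clone)
})
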