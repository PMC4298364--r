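# Shared fixture builders. All fixtures are generated in code; the small
# "desk" scale (2,000 adult cells) is the package's standard reduced scale
# for stochastic checks.

desk_schedules <- function(adult_size = 2000, ...) {
  hsc_schedules(adult_size = adult_size, ...)
}

# tiny pool + short life for fast engine unit tests
tiny_config <- function(...) {
  defaults <- list(
    lifespan_weeks = 120,
    initial_cells = 50,
    schedules = hsc_schedules(initial_cells = 50, adult_size = 300),
    seed = 1
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# schedules with a constant division probability (d0 == d_adult)
flat_division_schedules <- function(p, adult_size = 1000,
                                    initial_cells = 300) {
  hsc_schedules(initial_cells = initial_cells, adult_size = adult_size,
                d0 = p, d_adult = p)
}

# deterministic mean over a few replicate simulations
replicate_stat <- function(config, seeds, fn) {
  vapply(seeds, function(s) {
    config$seed <- s
    fn(run_simulation(config))
  }, numeric(1))
}

# expensive shared objects for the acceptance suite, built once per test run
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_sigma_grid <- function() exp(seq(log(5e-6), log(5e-1), length.out = 6))
acceptance_fold_grid <- function() 1:8

acceptance_sweep_mut <- function() {
  if (is.null(.acceptance_cache$mut)) {
    base <- preset_config("mutations_only", schedules = desk_schedules(),
                          seed = 11)
    base$dfe$positive_tail_fraction <- 0.01
    .acceptance_cache$mut <- run_grid(base, acceptance_sigma_grid(),
                                      acceptance_fold_grid(), replicates = 3)
  }
  .acceptance_cache$mut
}

acceptance_sweep_comp <- function() {
  if (is.null(.acceptance_cache$comp)) {
    base <- preset_config("composite", schedules = desk_schedules(),
                          seed = 11)
    base$dfe$positive_tail_fraction <- 0
    base$env$positive_tail_fraction <- 0
    .acceptance_cache$comp <- run_grid(base, acceptance_sigma_grid(),
                                       acceptance_fold_grid(), replicates = 3)
  }
  .acceptance_cache$comp
}
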