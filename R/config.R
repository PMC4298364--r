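#' Full simulation configuration
#'
#' Bundles every parameter of a run: lifespan, initial pool, DFE, environment,
#' demography schedules, clone threshold, seed and recording cadence. If the
#' DFE's Tier-3 rate is unset it is calibrated here (via
#' [calibrate_tier3_rate()]) so that the analytic neutral accumulation slope
#' at a stable mutation rate equals the AML reference slope
#' (0.09162 mutations/year); the calibrated value is recorded in the returned
#' object.
#'
#' @param lifespan_weeks Simulated lifespan in weeks (default 4420 = 85 y).
#' @param initial_cells Starting pool size (default 300).
#' @param initial_clones `"per_cell"` (each initial cell founds a clone) or
#'   `"single"` (one ancestral clone).
#' @param dfe A [dfe_spec()].
#' @param env An [env_spec()]; disabled by default (mutations-only model).
#' @param schedules An [hsc_schedules()].
#' @param clone_threshold Fitness-divergence threshold for designating new
#'   clones (default 0.05).
#' @param seed Integer seed for the run's named RNG streams.
#' @param record_cadence Weeks between trajectory samples (default 1).
#' @param division_mode `"symmetric"` (mother replaced by two daughters,
#'   default) or `"asymmetric"` (mother persists, one daughter added).
#' @param weight_floor Minimum competition weight (default 1e-6).
#' @param preset Optional preset label carried for provenance.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(lifespan_weeks = 4420,
                       initial_cells = 300,
                       initial_clones = c("per_cell", "single"),
                       dfe = dfe_spec(),
                       env = env_spec(enabled = FALSE),
                       schedules = hsc_schedules(),
                       clone_threshold = 0.05,
                       seed = 1,
                       record_cadence = 1,
                       division_mode = c("symmetric", "asymmetric"),
                       weight_floor = 1e-6,
                       preset = NA_character_) {
  initial_clones <- match.arg(initial_clones)
  division_mode <- match.arg(division_mode)
  stopifnot(inherits(dfe, "dfe_spec"), inherits(env, "env_spec"),
            inherits(schedules, "hsc_schedules"))
  if (lifespan_weeks < 0 || lifespan_weeks != round(lifespan_weeks))
    stop("`lifespan_weeks` must be a non-negative integer", call. = FALSE)
  if (initial_cells <= 0)
    stop("`initial_cells` must be positive", call. = FALSE)
  if (clone_threshold <= 0)
    stop("`clone_threshold` must be > 0", call. = FALSE)
  if (record_cadence < 1)
    stop("`record_cadence` must be >= 1", call. = FALSE)
  calibrated <- FALSE
  if (is.null(dfe$tier3_rate_per_division)) {
    dfe$tier3_rate_per_division <- calibrate_tier3_rate(
      schedules, lifespan_weeks = max(lifespan_weeks, 1),
      division_mode = division_mode)
    calibrated <- TRUE
  }
  structure(
    list(
      lifespan_weeks = as.integer(lifespan_weeks),
      initial_cells = as.integer(initial_cells),
      initial_clones = initial_clones,
      dfe = dfe, env = env, schedules = schedules,
      clone_threshold = clone_threshold,
      seed = as.integer(seed),
      record_cadence = as.integer(record_cadence),
      division_mode = division_mode,
      weight_floor = weight_floor,
      preset = preset,
      tier3_rate_calibrated = calibrated
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      if (!is.na(x$preset)) paste0("preset '", x$preset, "',") else "",
      x$lifespan_weeks, "weeks,", x$initial_cells, "initial cells, seed",
      x$seed, "\n")
  print(x$dfe)
  print(x$env)
  print(x$schedules)
  invisible(x)
}

#' Named replication presets
#'
#' Complete configurations for the study's headline conditions:
#' * `"mutations_only"` - cell fitness set by mutations alone (environment
#'   off), DFE positive tail 1%, stable 11,000-cell adult pool.
#' * `"composite"` - mutations plus the bicomponent microenvironment model;
#'   mutation positive tail 0% (the composite-model convention), distributed
#'   environmental component zero-centred.
#' * `"slow_cycle"` - composite conditions under the slow adult cycling
#'   estimate (0.6 divisions/year), mutation tail 1%, environment tail 0%.
#' * `"pool_11k"` - explicit stable 11,000-cell demography variant.
#' * `"pool_11k_to_25k"` - adult pool grows linearly from 11,000 to 25,000
#'   cells over adulthood; mutation tail 1%, environment tail 0%.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [sim_config()] (e.g. `seed`,
#'   `lifespan_weeks`, `schedules`).
#' @return A validated [sim_config()].
#' @export
preset_config <- function(name = c("mutations_only", "composite", "slow_cycle",
                                   "pool_11k", "pool_11k_to_25k"),
                          ...) {
  name <- match.arg(name)
  base <- switch(name,
    mutations_only = list(
      dfe = dfe_spec(sigma = 5e-5, positive_tail_fraction = 0.01),
      env = env_spec(enabled = FALSE),
      schedules = hsc_schedules(preset = "stable")
    ),
    composite = list(
      dfe = dfe_spec(sigma = 5e-5, positive_tail_fraction = 0),
      env = env_spec(enabled = TRUE, positive_tail_fraction = 0.5),
      schedules = hsc_schedules(preset = "stable")
    ),
    slow_cycle = list(
      dfe = dfe_spec(sigma = 5e-5, positive_tail_fraction = 0.01),
      env = env_spec(enabled = TRUE, positive_tail_fraction = 0),
      schedules = hsc_schedules(preset = "stable", cycling = "slow")
    ),
    pool_11k = list(
      dfe = dfe_spec(sigma = 5e-5, positive_tail_fraction = 0.01),
      env = env_spec(enabled = FALSE),
      schedules = hsc_schedules(preset = "stable", adult_size = 11000)
    ),
    pool_11k_to_25k = list(
      dfe = dfe_spec(sigma = 5e-5, positive_tail_fraction = 0.01),
      env = env_spec(enabled = TRUE, positive_tail_fraction = 0),
      schedules = hsc_schedules(preset = "growing")
    )
  )
  args <- utils::modifyList(base, list(...))
  args$preset <- name
  do.call(sim_config, args)
}

# serialization ----------------------------------------------------------------

config_to_list <- function(config) {
  list(
    preset = if (is.na(config$preset)) NULL else config$preset,
    engine = list(
      lifespan_weeks = config$lifespan_weeks,
      initial_cells = config$initial_cells,
      initial_clones = config$initial_clones,
      clone_threshold = config$clone_threshold,
      seed = config$seed,
      record_cadence = config$record_cadence,
      division_mode = config$division_mode,
      weight_floor = config$weight_floor
    ),
    dfe = list(
      sigma = config$dfe$sigma,
      positive_tail_fraction = config$dfe$positive_tail_fraction,
      rate_fold_increase = config$dfe$rate_fold_increase,
      tier3_rate_per_division = config$dfe$tier3_rate_per_division,
      ramp = config$dfe$ramp
    ),
    environment = list(
      enabled = config$env$enabled,
      f_max = config$env$f_max,
      f_min = config$env$f_min,
      scale = config$env$scale,
      rate = config$env$rate,
      positive_tail_fraction = config$env$positive_tail_fraction,
      spread = config$env$spread,
      persistent = config$env$persistent
    ),
    demography = list(
      preset = config$schedules$preset,
      cycling = config$schedules$cycling,
      initial_cells = config$schedules$initial_cells,
      adult_size = config$schedules$adult_size,
      adult_size_end = config$schedules$adult_size_end,
      maturity_weeks = config$schedules$maturity_weeks,
      growth_midpoint_weeks = config$schedules$growth_midpoint_weeks,
      d0 = config$schedules$d0,
      d_adult = config$schedules$d_adult,
      d_decay_per_week = config$schedules$d_decay_per_week,
      lifespan_weeks = config$schedules$lifespan_weeks
    )
  )
}

check_field <- function(ok, path, msg) {
  if (!ok) stop("config field `", path, "`: ", msg, call. = FALSE)
}

#' Save a configuration to a YAML file
#'
#' @param config A [sim_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration (blocks `engine`, `dfe`, `environment`,
#' `demography`, or just a `preset` name), fills defaults, validates with
#' field paths, and returns a complete [sim_config()]. A load -> save ->
#' load round trip is the identity.
#'
#' @param path Path to a YAML config file.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must parse to a mapping", call. = FALSE)

  d <- raw$dfe
  if (!is.null(d$sigma))
    check_field(is.numeric(d$sigma) && d$sigma >= 0, "dfe.sigma",
                "must be a non-negative number")
  if (!is.null(d$positive_tail_fraction))
    check_field(is.numeric(d$positive_tail_fraction) &&
                  d$positive_tail_fraction >= 0 && d$positive_tail_fraction <= 1,
                "dfe.positive_tail_fraction", "must be in [0, 1]")
  if (!is.null(d$rate_fold_increase))
    check_field(is.numeric(d$rate_fold_increase) && d$rate_fold_increase >= 1,
                "dfe.rate_fold_increase", "must be >= 1")
  e <- raw$environment
  if (!is.null(e$f_max) && !is.null(e$f_min))
    check_field(e$f_max > e$f_min && e$f_min > 0, "environment.f_min",
                "requires f_max > f_min > 0")
  g <- raw$engine
  if (!is.null(g$clone_threshold))
    check_field(is.numeric(g$clone_threshold) && g$clone_threshold > 0,
                "engine.clone_threshold", "must be > 0")
  if (!is.null(g$initial_cells))
    check_field(is.numeric(g$initial_cells) && g$initial_cells > 0,
                "engine.initial_cells", "must be positive")

  if (!is.null(raw$preset)) {
    base <- preset_config(raw$preset)
  } else {
    base <- sim_config()
  }
  dfe_args <- utils::modifyList(
    list(sigma = base$dfe$sigma,
         positive_tail_fraction = base$dfe$positive_tail_fraction,
         rate_fold_increase = base$dfe$rate_fold_increase,
         tier3_rate_per_division = base$dfe$tier3_rate_per_division,
         ramp = base$dfe$ramp),
    d %||% list())
  env_args <- utils::modifyList(
    list(enabled = base$env$enabled, f_max = base$env$f_max,
         f_min = base$env$f_min, scale = base$env$scale, rate = base$env$rate,
         positive_tail_fraction = base$env$positive_tail_fraction,
         spread = base$env$spread, persistent = base$env$persistent),
    e %||% list())
  sch_args <- utils::modifyList(
    list(preset = base$schedules$preset, cycling = base$schedules$cycling,
         initial_cells = base$schedules$initial_cells,
         adult_size = base$schedules$adult_size,
         adult_size_end = base$schedules$adult_size_end,
         maturity_weeks = base$schedules$maturity_weeks,
         growth_midpoint_weeks = base$schedules$growth_midpoint_weeks,
         d0 = base$schedules$d0, d_adult = base$schedules$d_adult,
         d_decay_per_week = base$schedules$d_decay_per_week,
         lifespan_weeks = base$schedules$lifespan_weeks),
    raw$demography %||% list())
  if (!is.null(sch_args$preset) &&
      !sch_args$preset %in% c("stable", "large", "growing"))
    stop("config field `demography.preset`: unknown preset '",
         sch_args$preset, "'", call. = FALSE)
  eng_args <- utils::modifyList(
    list(lifespan_weeks = base$lifespan_weeks,
         initial_cells = base$initial_cells,
         initial_clones = base$initial_clones,
         clone_threshold = base$clone_threshold,
         seed = base$seed, record_cadence = base$record_cadence,
         division_mode = base$division_mode,
         weight_floor = base$weight_floor),
    g %||% list())
  do.call(sim_config, c(
    eng_args,
    list(dfe = do.call(dfe_spec, dfe_args),
         env = do.call(env_spec, env_args),
         schedules = do.call(hsc_schedules, sch_args),
         preset = raw$preset %||% NA_character_)
  ))
}

#' Write the package's small reference fixtures
#'
#' Writes to `out_dir`: the default reference incidence curve
#' (`incidence_default.csv`), a noiseless linear Tier-3 fixture trajectory
#' with slope 0.09162 mutations/year (`tier3_linear_fixture.csv`), and a tiny
#' smoke-test configuration (`smoke_config.yaml`: 50 cells, 200 weeks).
#' Output is deterministic, so repeated calls are byte-identical.
#'
#' @param out_dir Writable output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inc_path <- file.path(out_dir, "incidence_default.csv")
  write_incidence_curve(default_incidence_curve(), inc_path)

  ages <- 0:85
  fix <- tibble::tibble(
    week = ages * 52,
    age_years = ages,
    pool_size = 11000,
    mean_fitness = 1,
    mean_tier3 = 0.09162 * ages,
    top_clone_share = 1 / 300,
    n_clones = 300
  )
  fix_path <- file.path(out_dir, "tier3_linear_fixture.csv")
  readr::write_csv(fix, fix_path)

  smoke <- sim_config(
    lifespan_weeks = 200, initial_cells = 50,
    schedules = hsc_schedules(initial_cells = 50, adult_size = 400),
    seed = 1
  )
  smoke_path <- file.path(out_dir, "smoke_config.yaml")
  save_config(smoke, smoke_path)
  invisible(c(inc_path, fix_path, smoke_path))
}
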