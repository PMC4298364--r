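# Named RNG streams -----------------------------------------------------------
#
# Four independent Mersenne-Twister states (division, dfe, environment,
# competition) derived from one top-level seed, so toggling one mechanism
# (e.g. disabling the microenvironment) does not shift the draws of another.

rng_streams <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  subs <- sample.int(.Machine$integer.max, 4L)
  names(subs) <- c("division", "dfe", "environment", "competition")
  for (nm in names(subs)) {
    set.seed(subs[[nm]])
    assign(nm, get(".Random.seed", globalenv()), envir = e)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  e
}

with_stream <- function(streams, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  out <- force(code)
  assign(name, get(".Random.seed", globalenv()), envir = streams)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

# Pool -------------------------------------------------------------------------

#' Initialize the HSC pool
#'
#' Creates the starting cell pool: `initial_cells` cells at fitness 1 with no
#' Tier-3 mutations, each founding its own clone (or all sharing a single
#' ancestral clone if `initial_clones = "single"`), at week 0, with fresh
#' named RNG streams seeded from the config seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `hsc_pool`: a list with per-cell vectors
#'   `fitness`, `tier3`, `clone`, a per-clone `founder_fitness` record, the
#'   current `week`, and internal RNG streams.
#' @export
initialize_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$initial_cells
  if (n <= 0) stop("`initial_cells` must be positive", call. = FALSE)
  clone <- if (config$initial_clones == "per_cell") seq_len(n)
           else rep(1L, n)
  n_clones <- max(clone)
  founder <- rep(1, n_clones)
  structure(
    list(
      fitness = rep(1, n),
      tier3 = rep(0, n),
      clone = as.integer(clone),
      env_dev = rep(0, n),
      founder_fitness = founder,
      next_clone = n_clones + 1L,
      cum_uniform_drop = 0,
      departures = 0L,
      week = 0L,
      streams = rng_streams(config$seed)
    ),
    class = "hsc_pool"
  )
}

#' @export
print.hsc_pool <- function(x, ...) {
  cat("<hsc_pool> week", x$week, "-", length(x$fitness), "cells,",
      length(unique(x$clone)), "clones\n")
  if (length(x$fitness))
    cat("  mean fitness", format(mean(x$fitness), digits = 4),
        "| mean tier3", format(mean(x$tier3), digits = 4), "\n")
  invisible(x)
}

# grow the per-clone founder record geometrically
ensure_founder_capacity <- function(pool, needed) {
  cur <- length(pool$founder_fitness)
  if (needed > cur) {
    new_len <- max(needed, 2L * cur)
    pool$founder_fitness <- c(pool$founder_fitness,
                              rep(NA_real_, new_len - cur))
  }
  pool
}

#' Assign clone labels to daughters after division
#'
#' A daughter whose fitness has diverged from her clone founder's recorded
#' fitness by more than the threshold `theta` founds a new clone, with the
#' daughter's current fitness as the new founder record. Divergence is
#' measured on microenvironment-detrended fitness: the uniform weekly drop
#' affects every cell identically and carries no clonal information, so the
#' cumulative uniform drop since the clone's founding is excluded (with the
#' environment disabled this is the plain founder-referenced rule).
#'
#' @param fitness Daughters' fitness values.
#' @param clone Daughters' inherited clone ids.
#' @param founder_fitness Per-clone founder record (detrended scale).
#' @param theta Clone-divergence threshold (> 0).
#' @param next_clone First free clone id.
#' @param detrend Cumulative uniform drop to add back to `fitness` before
#'   comparison (0 when the environment is off).
#' @return A list with elements `clone` (updated labels), `founder_fitness`
#'   (records for any new clones, named by id), `next_clone`.
#' @export
assign_clones <- function(fitness, clone, founder_fitness, theta,
                          next_clone, detrend = 0) {
  if (theta <= 0) stop("clone threshold `theta` must be > 0", call. = FALSE)
  detr <- fitness + detrend
  dev <- abs(detr - founder_fitness[clone])
  idx <- which(dev > theta)
  new_records <- numeric(0)
  if (length(idx)) {
    ids <- next_clone + seq_along(idx) - 1L
    clone[idx] <- ids
    new_records <- stats::setNames(detr[idx], ids)
    next_clone <- next_clone + length(idx)
  }
  list(clone = clone, founder_fitness = new_records, next_clone = next_clone)
}

#' Stochastic cell division with fitness and Tier-3 updates
#'
#' Each living cell divides with probability `d(t)` at the pool's current
#' week. Under `"symmetric"` division a dividing mother is replaced by two
#' daughters; under `"asymmetric"` the mother persists unchanged and one
#' daughter is added. Every new daughter inherits her mother's state, then
#' receives one independent net fitness effect from the DFE and one Poisson
#' Tier-3 increment, and is re-labelled by [assign_clones()] if she crossed
#' the clone threshold.
#'
#' @param pool An `hsc_pool`.
#' @param config A [sim_config()].
#' @return The updated pool (pre-competition; the pool may exceed capacity).
#' @export
divide_cells <- function(pool, config) {
  t <- pool$week
  n <- length(pool$fitness)
  if (n == 0L) return(pool)
  p <- division_probability(t, config$schedules)
  div <- with_stream(pool$streams, "division", stats::runif(n) < p)
  nd <- sum(div)
  if (nd == 0L) return(pool)
  idx <- which(div)
  k <- if (config$division_mode == "symmetric") 2L else 1L
  rep_idx <- rep(idx, k)
  eff <- with_stream(pool$streams, "dfe",
                     sample_fitness_effects(config$dfe, t,
                                            config$lifespan_weeks, k * nd))
  t3i <- with_stream(pool$streams, "dfe",
                     sample_tier3_counts(config$dfe, t,
                                         config$lifespan_weeks, k * nd))
  d_fit <- pool$fitness[rep_idx] + eff
  d_t3 <- pool$tier3[rep_idx] + t3i
  d_clone <- pool$clone[rep_idx]
  d_env <- pool$env_dev[rep_idx]

  ca <- assign_clones(d_fit, d_clone, pool$founder_fitness,
                      config$clone_threshold, pool$next_clone,
                      detrend = pool$cum_uniform_drop)
  d_clone <- ca$clone
  if (length(ca$founder_fitness)) {
    pool <- ensure_founder_capacity(pool, ca$next_clone - 1L)
    pool$founder_fitness[as.integer(names(ca$founder_fitness))] <-
      ca$founder_fitness
    pool$next_clone <- ca$next_clone
  }

  if (config$division_mode == "symmetric") {
    keep <- !div
    pool$fitness <- c(pool$fitness[keep], d_fit)
    pool$tier3 <- c(pool$tier3[keep], d_t3)
    pool$clone <- c(pool$clone[keep], d_clone)
    pool$env_dev <- c(pool$env_dev[keep], d_env)
  } else {
    pool$fitness <- c(pool$fitness, d_fit)
    pool$tier3 <- c(pool$tier3, d_t3)
    pool$clone <- c(pool$clone, d_clone)
    pool$env_dev <- c(pool$env_dev, d_env)
  }
  pool
}

#' Fitness-weighted niche competition
#'
#' If the pool exceeds the carrying capacity `N(t)`, exactly
#' `n - N(t)` cells are removed. Survivors are drawn without replacement with
#' selection weight proportional to fitness (floored at a small epsilon),
#' using the exponential-key construction: cell `i` survives iff its key
#' `Exp(1)/w_i` ranks among the `N(t)` smallest, which is distributionally
#' identical to successive weighted draws without replacement.
#'
#' @inheritParams divide_cells
#' @return The pool with at most `N(t)` cells; removals are counted as
#'   departures.
#' @export
apply_competition <- function(pool, config) {
  n <- length(pool$fitness)
  N <- carrying_capacity(pool$week, config$schedules)
  if (N <= 0) stop("carrying capacity must be positive", call. = FALSE)
  if (n <= N) return(pool)
  w <- pmax(pool$fitness, config$weight_floor)
  keys <- with_stream(pool$streams, "competition", stats::rexp(n)) / w
  # cells with the N smallest keys survive; partial sort finds the cutoff
  kth <- sort.int(keys, partial = N)[N]
  survivors <- which(keys <= kth)
  if (length(survivors) > N) survivors <- survivors[seq_len(N)]
  pool$departures <- pool$departures + (n - N)
  pool$fitness <- pool$fitness[survivors]
  pool$tier3 <- pool$tier3[survivors]
  pool$clone <- pool$clone[survivors]
  pool$env_dev <- pool$env_dev[survivors]
  pool
}

# drop cells whose fitness has reached zero or below (loss of viability)
remove_nonviable <- function(pool) {
  alive <- pool$fitness > 0
  if (all(alive)) return(pool)
  pool$departures <- pool$departures + sum(!alive)
  pool$fitness <- pool$fitness[alive]
  pool$tier3 <- pool$tier3[alive]
  pool$clone <- pool$clone[alive]
  pool$env_dev <- pool$env_dev[alive]
  pool
}

apply_environment <- function(pool, config) {
  env <- config$env
  if (!env$enabled) return(pool)
  t <- pool$week
  n <- length(pool$fitness)
  dF <- weekly_fitness_drop(t, env)
  draws <- with_stream(pool$streams, "environment",
                       sample_env_effects(t, n, env))
  if (env$persistent) {
    pool$fitness <- pool$fitness - dF + draws
  } else {
    pool$fitness <- pool$fitness - dF - pool$env_dev + draws
    pool$env_dev <- draws
  }
  pool$cum_uniform_drop <- pool$cum_uniform_drop + dF
  pool
}

#' Advance the pool by one week
#'
#' Applies, in a fixed order: stochastic division (with DFE draws, Tier-3
#' accrual and clone assignment), the uniform microenvironmental fitness drop
#' plus distributed per-cell draws (if the environment is enabled), removal
#' of cells with fitness at or below zero, and fitness-weighted competition
#' down to the carrying capacity. The week counter then advances. Results
#' are order-sensitive, so the order is part of the model definition.
#'
#' @inheritParams divide_cells
#' @return The pool at `week + 1`.
#' @export
step_week <- function(pool, config) {
  if (pool$week >= config$lifespan_weeks)
    stop("pool is already at the end of the configured lifespan", call. = FALSE)
  pool <- divide_cells(pool, config)
  pool <- apply_environment(pool, config)
  pool <- remove_nonviable(pool)
  pool <- apply_competition(pool, config)
  pool$week <- pool$week + 1L
  pool
}

pool_metrics <- function(pool) {
  n <- length(pool$fitness)
  if (n == 0L) {
    return(c(pool_size = 0, mean_fitness = NA_real_, mean_tier3 = NA_real_,
             top_clone_share = NA_real_, n_clones = 0))
  }
  counts <- tabulate(match(pool$clone, unique(pool$clone)))
  c(pool_size = n,
    mean_fitness = mean(pool$fitness),
    mean_tier3 = mean(pool$tier3),
    top_clone_share = max(counts) / n,
    n_clones = length(counts))
}

#' Run a full simulation
#'
#' Iterates [step_week()] from week 0 through `lifespan_weeks`, recording the
#' trajectory (pool size, mean fitness, mean Tier-3 count, largest-clone
#' share, clone count) every `record_cadence` weeks (the initial state and
#' the final week are always recorded). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `hsc_sim` with elements `trajectory` (a tibble
#'   with columns `week`, `age_years`, `pool_size`, `mean_fitness`,
#'   `mean_tier3`, `top_clone_share`, `n_clones`), `config`, and `final_pool`.
#' @examples
#' cfg <- sim_config(lifespan_weeks = 100, initial_cells = 50,
#'                   schedules = hsc_schedules(adult_size = 400), seed = 1)
#' sim <- run_simulation(cfg)
#' tail(tidy(sim))
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pool <- initialize_pool(config)
  L <- config$lifespan_weeks
  cad <- config$record_cadence
  rec_weeks <- unique(c(seq(0L, L, by = cad), L))
  nrec <- length(rec_weeks)
  out <- matrix(NA_real_, nrow = nrec, ncol = 5L)
  ri <- 1L
  out[ri, ] <- pool_metrics(pool)
  if (L > 0) {
    for (t in seq_len(L)) {
      pool <- step_week(pool, config)
      if (ri < nrec && t == rec_weeks[ri + 1L]) {
        ri <- ri + 1L
        out[ri, ] <- pool_metrics(pool)
      }
    }
  }
  traj <- tibble::tibble(
    week = rec_weeks,
    age_years = rec_weeks / 52,
    pool_size = out[, 1],
    mean_fitness = out[, 2],
    mean_tier3 = out[, 3],
    top_clone_share = out[, 4],
    n_clones = out[, 5]
  )
  structure(
    list(trajectory = traj, config = config, final_pool = pool),
    class = "hsc_sim"
  )
}

#' @export
print.hsc_sim <- function(x, ...) {
  g <- glance(x)
  cat("<hsc_sim>", x$config$lifespan_weeks, "weeks, seed",
      x$config$seed, "\n")
  cat("  final pool:", g$pool_size, "cells | mean fitness",
      format(g$end_fitness, digits = 4), "| mean tier3",
      format(g$end_tier3, digits = 4), "\n")
  cat("  tier3 slope", format(g$tier3_slope, digits = 4),
      "/yr | top clone", format(g$expansion_pct, digits = 4), "%\n")
  invisible(x)
}

#' @rdname run_simulation
#' @param x An `hsc_sim` object.
#' @param ... Unused.
#' @export
tidy.hsc_sim <- function(x, ...) x$trajectory

#' @rdname run_simulation
#' @export
glance.hsc_sim <- function(x, ...) {
  traj <- x$trajectory
  last <- traj[nrow(traj), ]
  sl <- tryCatch(tier3_slope(traj)$estimate, error = function(e) NA_real_)
  tibble::tibble(
    weeks = x$config$lifespan_weeks,
    pool_size = last$pool_size,
    end_fitness = last$mean_fitness,
    end_tier3 = last$mean_tier3,
    tier3_slope = sl,
    expansion_pct = end_of_life_expansion(traj),
    n_clones = last$n_clones,
    departures = x$final_pool$departures
  )
}
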