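#' Age-dependent demography schedules for the HSC pool
#'
#' Carrying capacity `N(t)` and expected weekly division probability `d(t)`
#' as functions of age in weeks. The pool grows along a logistic-type curve
#' from 300 cells at birth to the adult size by maturity (default 18 years),
#' then follows the preset: constant 11,000 (`"stable"`), constant 25,000
#' (`"large"`), or linear growth 11,000 to 25,000 across adulthood
#' (`"growing"`). The division probability decays exponentially from a rapid
#' early-life rate (default 0.4/week) to the adult plateau (default 1/40 per
#' week, about 1.3 divisions/year); the `"slow"` cycling variant plateaus at
#' 0.6 divisions/year (0.6/52 per week), the lowest published adult estimate.
#'
#' These parametric curves reconstruct the qualitative published dynamics
#' (rapid early-life cycling and pool growth, stable slow-cycling adulthood);
#' the exact numeric curves behind them are not published, so every breakpoint
#' is a configurable parameter.
#'
#' @param preset Capacity preset: `"stable"`, `"large"`, or `"growing"`.
#' @param cycling Division-rate preset: `"default"` or `"slow"`.
#' @param initial_cells Pool size at birth (default 300).
#' @param adult_size Adult carrying capacity for the `"stable"` preset and the
#'   start of adulthood for `"growing"` (default 11000).
#' @param adult_size_end End-of-life capacity for the `"growing"` preset
#'   (default 25000); ignored otherwise.
#' @param maturity_weeks Age at which the pool reaches the adult size
#'   (default 936 weeks = 18 years).
#' @param growth_midpoint_weeks Midpoint of the logistic growth phase
#'   (default 468 weeks = 9 years).
#' @param d0 Division probability per week at birth (default 0.4).
#' @param d_adult Adult plateau division probability per week; defaults to
#'   1/40 (`cycling = "default"`) or 0.6/52 (`cycling = "slow"`).
#' @param d_decay_per_week Exponential decay rate of the early-life excess
#'   division probability; the default reaches within 1% of the plateau by
#'   age 20 (1040 weeks).
#' @param lifespan_weeks Lifespan used by the `"growing"` preset to place its
#'   end point (default 4420 weeks = 85 years).
#' @return An object of class `hsc_schedules`.
#' @examples
#' sch <- hsc_schedules()
#' carrying_capacity(0, sch)          # 300
#' carrying_capacity(2000, sch)       # 11000
#' division_probability(c(0, 4420), sch)
#' @export
hsc_schedules <- function(preset = c("stable", "large", "growing"),
                          cycling = c("default", "slow"),
                          initial_cells = 300,
                          adult_size = 11000,
                          adult_size_end = 25000,
                          maturity_weeks = 936,
                          growth_midpoint_weeks = 468,
                          d0 = 0.4,
                          d_adult = NULL,
                          d_decay_per_week = log(100) / 1040,
                          lifespan_weeks = 4420) {
  preset <- match.arg(preset)
  cycling <- match.arg(cycling)
  if (initial_cells <= 0) stop("`initial_cells` must be positive", call. = FALSE)
  if (adult_size < initial_cells)
    stop("`adult_size` must be at least `initial_cells`", call. = FALSE)
  if (preset == "large" && missing(adult_size)) adult_size <- 25000
  if (is.null(d_adult)) d_adult <- if (cycling == "slow") 0.6 / 52 else 1 / 40
  if (d0 < 0 || d0 > 1 || d_adult < 0 || d_adult > 1)
    stop("division probabilities must lie in [0, 1]", call. = FALSE)
  structure(
    list(
      preset = preset, cycling = cycling,
      initial_cells = as.integer(initial_cells),
      adult_size = as.integer(adult_size),
      adult_size_end = as.integer(adult_size_end),
      maturity_weeks = maturity_weeks,
      growth_midpoint_weeks = growth_midpoint_weeks,
      growth_rate = log(99) / (maturity_weeks - growth_midpoint_weeks),
      d0 = d0, d_adult = d_adult,
      d_decay_per_week = d_decay_per_week,
      lifespan_weeks = lifespan_weeks
    ),
    class = "hsc_schedules"
  )
}

#' @export
print.hsc_schedules <- function(x, ...) {
  cat("<hsc_schedules>", x$preset, "capacity,", x$cycling, "cycling\n")
  cat("  N(0) =", x$initial_cells, "-> adult", x$adult_size,
      if (x$preset == "growing") paste("->", x$adult_size_end) else "",
      "by week", x$maturity_weeks, "\n")
  cat("  d(0) =", format(x$d0), "/wk -> plateau", format(x$d_adult), "/wk\n")
  invisible(x)
}

#' Carrying capacity at a given age
#'
#' Pure function of `(t, schedules)`: logistic-type growth from the initial
#' pool size at birth (exactly `initial_cells` at `t = 0`) to the adult size
#' at maturity, then the adult-phase rule of the preset.
#'
#' @param t Age in weeks (vectorised).
#' @param schedules An [hsc_schedules()] object.
#' @return Integer vector of positive capacities.
#' @export
carrying_capacity <- function(t, schedules) {
  stopifnot(inherits(schedules, "hsc_schedules"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  s <- schedules
  logi <- function(x) 1 / (1 + exp(-s$growth_rate * (x - s$growth_midpoint_weeks)))
  # rescale so the curve is anchored exactly at N(0) and N(maturity)
  g <- (logi(pmin(t, s$maturity_weeks)) - logi(0)) /
       (logi(s$maturity_weeks) - logi(0))
  adult_at <- function(x) {
    if (s$preset == "growing") {
      span <- max(s$lifespan_weeks - s$maturity_weeks, 1)
      frac <- pmin(pmax((x - s$maturity_weeks) / span, 0), 1)
      s$adult_size + (s$adult_size_end - s$adult_size) * frac
    } else {
      rep(s$adult_size, length(x))
    }
  }
  grown <- s$initial_cells + (s$adult_size - s$initial_cells) * pmin(pmax(g, 0), 1)
  out <- ifelse(t < s$maturity_weeks, grown, adult_at(t))
  as.integer(round(out))
}

#' Weekly division probability at a given age
#'
#' Pure function of `(t, schedules)`: exponential decay from the early-life
#' rate to the adult plateau, `d(t) = d_adult + (d0 - d_adult) * exp(-k t)`;
#' non-increasing in age.
#'
#' @inheritParams carrying_capacity
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
division_probability <- function(t, schedules) {
  stopifnot(inherits(schedules, "hsc_schedules"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  s <- schedules
  s$d_adult + (s$d0 - s$d_adult) * exp(-s$d_decay_per_week * t)
}

#' Expected cumulative divisions per cell
#'
#' Running sum of the weekly division probability over integer weeks
#' `0, 1, ..., weeks - 1`; element `i` is the expected number of divisions a
#' cell lineage has undergone by the start of week `i`.
#'
#' @param schedules An [hsc_schedules()] object.
#' @param weeks Number of weeks.
#' @return Numeric vector of length `weeks + 1` starting at 0.
#' @export
cumulative_divisions <- function(schedules, weeks) {
  d <- division_probability(seq_len(weeks) - 1, schedules)
  c(0, cumsum(d))
}

#' Calibrate the Tier-3 passenger rate to a target accumulation slope
#'
#' Finds the per-division Tier-3 rate `mu0` such that the ordinary
#' least-squares slope (per year, over the whole lifespan) of the analytic
#' expected mean Tier-3 count under a stable mutation rate equals
#' `target_slope`. The analytic population-mean weekly increment under
#' symmetric division is `mu0 * 2 d(t) / (1 + d(t))` (each divider is
#' replaced by two daughters, each drawing one increment, before neutral
#' culling); under asymmetric division it is `mu0 * d(t) / (1 + d(t))`.
#'
#' The default target is the reference AML Tier-3 accumulation slope,
#' 0.09162 mutations/year (95% CI 0.03759-0.1457).
#'
#' @param schedules An [hsc_schedules()] object.
#' @param lifespan_weeks Lifespan in weeks (default 4420).
#' @param target_slope Target slope in mutations per year.
#' @param division_mode `"symmetric"` (default) or `"asymmetric"`.
#' @return The calibrated `mu0` (expected Tier-3 mutations per division at a
#'   stable rate).
#' @export
calibrate_tier3_rate <- function(schedules, lifespan_weeks = 4420,
                                 target_slope = 0.09162,
                                 division_mode = c("symmetric", "asymmetric")) {
  division_mode <- match.arg(division_mode)
  curve <- expected_tier3_curve(schedules, lifespan_weeks, mu0 = 1, fold = 1,
                                ramp = "linear", division_mode = division_mode)
  years <- (0:lifespan_weeks) / 52
  b <- stats::cov(years, curve) / stats::var(years)
  target_slope / b
}

# Analytic expected population-mean Tier-3 curve, weeks 0..lifespan.
expected_tier3_curve <- function(schedules, lifespan_weeks, mu0, fold,
                                 ramp = "linear",
                                 division_mode = "symmetric") {
  t <- seq_len(lifespan_weeks) - 1
  d <- division_probability(t, schedules)
  m <- relative_mutation_rate(t, lifespan_weeks, fold, ramp)
  inc <- if (division_mode == "symmetric") 2 * d / (1 + d) else d / (1 + d)
  c(0, cumsum(mu0 * m * inc))
}

#' Export schedules as a tidy table
#'
#' @param schedules An [hsc_schedules()] object.
#' @param weeks Number of weeks to tabulate (default the schedule's lifespan).
#' @return A tibble with columns `week`, `capacity`, `division_probability`.
#' @export
schedule_table <- function(schedules, weeks = schedules$lifespan_weeks) {
  t <- 0:weeks
  tibble::tibble(
    week = t,
    capacity = carrying_capacity(t, schedules),
    division_probability = division_probability(t, schedules)
  )
}
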