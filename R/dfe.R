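#' Mutation distribution of fitness effects (DFE) specification
#'
#' Defines the per-division net fitness-effect distribution for HSC divisions:
#' a zero-centred sign-mixture of half-normals with standard deviation `sigma`
#' and a configurable fraction of probability mass in the positive (beneficial)
#' tail, together with a lifetime mutation-rate ramp and the neutral Tier-3
#' passenger-mutation rate.
#'
#' @param sigma DFE standard deviation, in fitness units per division.
#'   The studied range is 5e-6 to 5e-1; `sigma = 0` gives a neutral model.
#' @param positive_tail_fraction Fraction of non-zero-effect probability mass
#'   assigned a positive sign, in `[0, 1]`. With 0.5 the draw is
#'   distributionally a zero-mean normal.
#' @param rate_fold_increase Mutation-rate multiplier reached at the end of
#'   life (>= 1). The per-week relative rate ramps from 1 at birth to this
#'   value at `lifespan`.
#' @param tier3_rate_per_division Expected Tier-3 (selectively neutral
#'   passenger) mutations per division at birth. `NULL` means "calibrate at
#'   config construction" so the neutral accumulation slope matches the AML
#'   reference slope (see [calibrate_tier3_rate()]).
#' @param ramp Shape of the mutation-rate ramp: `"linear"` (default) or
#'   `"exponential"`.
#' @return An object of class `dfe_spec`.
#' @examples
#' spec <- dfe_spec(sigma = 5e-4, positive_tail_fraction = 0.01)
#' effective_sigma(spec, t = 0, lifespan = 4420)
#' @export
dfe_spec <- function(sigma = 5e-5,
                     positive_tail_fraction = 0.01,
                     rate_fold_increase = 1,
                     tier3_rate_per_division = NULL,
                     ramp = c("linear", "exponential")) {
  ramp <- match.arg(ramp)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(positive_tail_fraction) || length(positive_tail_fraction) != 1L ||
      is.na(positive_tail_fraction) ||
      positive_tail_fraction < 0 || positive_tail_fraction > 1)
    stop("`positive_tail_fraction` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(rate_fold_increase) || length(rate_fold_increase) != 1L ||
      is.na(rate_fold_increase) || rate_fold_increase < 1)
    stop("`rate_fold_increase` must be >= 1", call. = FALSE)
  if (!is.null(tier3_rate_per_division)) {
    if (!is.numeric(tier3_rate_per_division) || length(tier3_rate_per_division) != 1L ||
        is.na(tier3_rate_per_division) || tier3_rate_per_division < 0)
      stop("`tier3_rate_per_division` must be a single non-negative number",
           call. = FALSE)
  }
  structure(
    list(
      sigma = as.numeric(sigma),
      positive_tail_fraction = as.numeric(positive_tail_fraction),
      rate_fold_increase = as.numeric(rate_fold_increase),
      tier3_rate_per_division = tier3_rate_per_division,
      ramp = ramp
    ),
    class = "dfe_spec"
  )
}

#' @export
print.dfe_spec <- function(x, ...) {
  cat("<dfe_spec>\n")
  cat("  sigma:                  ", format(x$sigma), "\n")
  cat("  positive tail fraction: ", format(x$positive_tail_fraction), "\n")
  cat("  rate fold increase:     ", format(x$rate_fold_increase),
      paste0("(", x$ramp, " ramp)"), "\n")
  cat("  tier3 rate / division:  ",
      if (is.null(x$tier3_rate_per_division)) "(calibrated at config build)"
      else format(x$tier3_rate_per_division), "\n")
  invisible(x)
}

#' Relative mutation rate over the lifespan
#'
#' Ramp of the per-division mutation rate relative to birth: 1 at `t = 0`,
#' `fold` at `t = lifespan`, monotone non-decreasing in between. The default
#' ramp is linear in age; an exponential alternative
#' `fold^(t / lifespan)` is available.
#'
#' @param t Age in weeks (vectorised).
#' @param lifespan Lifespan in weeks.
#' @param fold Fold increase reached at the end of life (>= 1).
#' @param ramp `"linear"` or `"exponential"`.
#' @return Numeric vector `m(t) >= 1`.
#' @examples
#' relative_mutation_rate(2210, 4420, fold = 5) # 3
#' @export
relative_mutation_rate <- function(t, lifespan, fold, ramp = c("linear", "exponential")) {
  ramp <- match.arg(ramp)
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be non-negative", call. = FALSE)
  if (any(t > lifespan, na.rm = TRUE))
    stop("`t` must not exceed `lifespan`", call. = FALSE)
  if (!is.numeric(fold) || any(fold < 1)) stop("`fold` must be >= 1", call. = FALSE)
  frac <- if (lifespan > 0) t / lifespan else rep(0, length(t))
  switch(ramp,
    linear = 1 + (fold - 1) * frac,
    exponential = fold^frac
  )
}

#' Effective DFE standard deviation at a given age
#'
#' An increased mutation rate widens the per-division net-effect distribution:
#' treating the net effect as the sum of `m(t)` independent unit-rate draws,
#' variances add, so the effective standard deviation is
#' `sigma * sqrt(m(t))`.
#'
#' @param spec A [dfe_spec()].
#' @param t Age in weeks (vectorised).
#' @param lifespan Lifespan in weeks.
#' @return Numeric vector of effective standard deviations.
#' @export
effective_sigma <- function(spec, t, lifespan) {
  stopifnot(inherits(spec, "dfe_spec"))
  m <- relative_mutation_rate(t, lifespan, spec$rate_fold_increase, spec$ramp)
  spec$sigma * sqrt(m)
}

# Sign-mixture of half-normals: magnitude |N(0, sd)|, sign +1 with
# probability `tail`. Shared by the mutation DFE and the microenvironment
# distributed component.
sample_sign_mixture <- function(n, sd, tail) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  mag <- abs(stats::rnorm(n, 0, sd))
  sgn <- ifelse(stats::runif(n) < tail, 1, -1)
  sgn * mag
}

#' Sample per-division net fitness effects
#'
#' Draws `n` independent net fitness changes from the DFE at age `t`:
#' magnitude `|N(0, effective_sigma(spec, t, lifespan))|` with sign +1 with
#' probability `positive_tail_fraction` and -1 otherwise. With tail fraction
#' 0.5 this is distributionally a zero-mean normal; with tail 0 every draw is
#' non-positive (cells can still differ by being "less negatively" affected).
#'
#' Draws come from the current RNG state; the simulation engine routes them
#' through a dedicated stream (see [run_simulation()]).
#'
#' @inheritParams effective_sigma
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_fitness_effects <- function(spec, t, lifespan, n) {
  stopifnot(inherits(spec, "dfe_spec"))
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  sample_sign_mixture(as.integer(n), effective_sigma(spec, t, lifespan),
                      spec$positive_tail_fraction)
}

#' Sample Tier-3 passenger-mutation increments
#'
#' Per-division Tier-3 increments are Poisson with mean
#' `mu0 * m(t)` where `mu0` is the birth rate per division and `m(t)` the
#' relative mutation rate. Counts accumulate on the daughter's inherited
#' count in the engine.
#'
#' @inheritParams sample_fitness_effects
#' @param n_divisions Number of division events to draw increments for.
#' @return Integer vector of non-negative counts.
#' @export
sample_tier3_counts <- function(spec, t, lifespan, n_divisions) {
  stopifnot(inherits(spec, "dfe_spec"))
  if (n_divisions < 0) stop("`n_divisions` must be non-negative", call. = FALSE)
  mu0 <- spec$tier3_rate_per_division
  if (is.null(mu0))
    stop("`tier3_rate_per_division` is unset; build the spec through ",
         "`sim_config()` to calibrate it", call. = FALSE)
  if (mu0 < 0) stop("`tier3_rate_per_division` must be >= 0", call. = FALSE)
  m <- relative_mutation_rate(t, lifespan, spec$rate_fold_increase, spec$ramp)
  stats::rpois(as.integer(n_divisions), mu0 * m)
}
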