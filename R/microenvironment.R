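#' Microenvironment specification
#'
#' Parameters of the bicomponent age-dependent microenvironmental fitness
#' modification: a uniform weekly decline shared by every cell, derived from
#' a logistic mean-fitness curve
#' `F(A) = f_max - (f_max - f_min) / (1 + scale * exp(-rate * A))`
#' (about a 3-fold drop from 1 to 0.3 over an 85-year life with the
#' defaults), plus a distributed per-cell perturbation drawn each week from a
#' zero-centred sign-mixture with spread `dF(t)/2`, where `dF(t)` is the
#' weekly decline of `F`.
#'
#' @param f_max Maximum initial fitness (default 1).
#' @param f_min Minimum end-life fitness (default 0.3).
#' @param scale Logistic prefactor (default 5200).
#' @param rate Logistic rate per week (default 0.0031).
#' @param positive_tail_fraction Fraction of the distributed component's mass
#'   given a positive sign (default 0.5, i.e. a zero-mean normal).
#' @param enabled If `FALSE` the module contributes nothing (mutations-only
#'   model).
#' @param spread Interpretation of `dF(t)/2` for the distributed component:
#'   `"sd"` (default; the curve parameter is a standard deviation) or
#'   `"variance"`.
#' @param persistent If `TRUE` (default) weekly distributed draws accumulate
#'   on each cell's fitness (a per-lineage random walk); if `FALSE` each
#'   week's draw replaces the previous one (transient re-valuation).
#' @return An object of class `env_spec`.
#' @examples
#' env <- env_spec()
#' mean_fitness_curve(c(0, 4420), env)
#' @export
env_spec <- function(f_max = 1, f_min = 0.3, scale = 5200, rate = 0.0031,
                     positive_tail_fraction = 0.5, enabled = TRUE,
                     spread = c("sd", "variance"), persistent = TRUE) {
  spread <- match.arg(spread)
  if (!(f_max > f_min) || f_min <= 0)
    stop("require `f_max > f_min > 0`", call. = FALSE)
  if (scale <= 0 || rate <= 0)
    stop("`scale` and `rate` must be positive", call. = FALSE)
  if (positive_tail_fraction < 0 || positive_tail_fraction > 1)
    stop("`positive_tail_fraction` must be in [0, 1]", call. = FALSE)
  structure(
    list(f_max = f_max, f_min = f_min, scale = scale, rate = rate,
         positive_tail_fraction = positive_tail_fraction,
         enabled = isTRUE(enabled), spread = spread,
         persistent = isTRUE(persistent)),
    class = "env_spec"
  )
}

#' @export
print.env_spec <- function(x, ...) {
  cat("<env_spec>", if (x$enabled) "enabled" else "disabled", "\n")
  cat("  F(A) =", format(x$f_max), "- (", format(x$f_max - x$f_min),
      ") / (1 +", format(x$scale), "* exp(-", format(x$rate), "* A))\n")
  cat("  distributed tail fraction:", format(x$positive_tail_fraction),
      paste0("(", x$spread, " = dF/2, ",
             if (x$persistent) "persistent" else "transient", ")\n"))
  invisible(x)
}

#' Age-dependent mean-fitness curve
#'
#' `F(A) = f_max - (f_max - f_min) / (1 + scale * exp(-rate * A))`, strictly
#' decreasing from approximately `f_max` at birth to `f_min` as age grows.
#'
#' @param A Age in weeks (vectorised).
#' @param spec An [env_spec()].
#' @return Numeric vector of mean fitness values.
#' @export
mean_fitness_curve <- function(A, spec) {
  stopifnot(inherits(spec, "env_spec"))
  if (any(A < 0)) stop("`A` must be non-negative", call. = FALSE)
  spec$f_max - (spec$f_max - spec$f_min) /
    (1 + spec$scale * exp(-spec$rate * A))
}

#' Weekly uniform fitness drop
#'
#' Magnitude of the per-week decline of the mean-fitness curve at week `t`,
#' from the analytic derivative
#' `|dF/dA| = (f_max - f_min) * scale * rate * exp(-rate A) /
#' (1 + scale * exp(-rate A))^2`. Subtracted uniformly from every living
#' cell's fitness at each weekly update when the environment is enabled.
#'
#' @param t Age in weeks (vectorised).
#' @inheritParams mean_fitness_curve
#' @return Numeric vector `dF(t) >= 0`.
#' @export
weekly_fitness_drop <- function(t, spec) {
  stopifnot(inherits(spec, "env_spec"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  e <- spec$scale * exp(-spec$rate * t)
  (spec$f_max - spec$f_min) * spec$rate * e / (1 + e)^2
}

#' Sample distributed microenvironmental fitness effects
#'
#' Per-cell weekly perturbations: sign-mixture draws (the same construction
#' as the mutation DFE) with spread parameter `dF(t)/2`. Under the default
#' `spread = "sd"` the half-normal magnitude scale is `dF(t)/2`; under
#' `"variance"` it is `sqrt(dF(t)/2)`.
#'
#' @param t Age in weeks.
#' @param n Number of draws.
#' @inheritParams mean_fitness_curve
#' @return Numeric vector of length `n`.
#' @export
sample_env_effects <- function(t, n, spec) {
  stopifnot(inherits(spec, "env_spec"))
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  half <- weekly_fitness_drop(t, spec) / 2
  sd <- if (spec$spread == "sd") half else sqrt(half)
  sample_sign_mixture(as.integer(n), sd, spec$positive_tail_fraction)
}

#' Export the environment curves as a tidy table
#'
#' @param spec An [env_spec()].
#' @param weeks Number of weeks to tabulate.
#' @return A tibble with columns `week`, `mean_fitness`, `weekly_drop`.
#' @export
env_table <- function(spec, weeks = 4420) {
  t <- 0:weeks
  tibble::tibble(
    week = t,
    mean_fitness = mean_fitness_curve(t, spec),
    weekly_drop = weekly_fitness_drop(t, spec)
  )
}
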