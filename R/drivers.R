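#' Multistage driver-acquisition model
#'
#' Heuristic for the probability that `n` successive driver events occur
#' within one cell lineage by time `t`:
#' `P(t) = D(t) * integral_0^t prod_i p_i(tau) d tau`,
#' where `D(t)` is the cumulative number of divisions in the pool by time `t`
#' and `p_i` the per-division probability of driver `i`. The quantity is a
#' rate-like heuristic used for relative reasoning (clones holding a larger
#' share of the pool have proportionally higher chances of completing the
#' driver set); it is not clamped at 1.
#'
#' @param p Per-driver per-division probabilities: a numeric vector of
#'   constants, or a list of functions of time. All values must lie in
#'   `[0, 1]`.
#' @param D Cumulative-divisions function of time: a single non-negative
#'   constant or a non-decreasing function.
#' @return An object of class `driver_model`.
#' @examples
#' m <- driver_model(p = c(1e-4, 1e-4), D = 1e6)
#' driver_probability(m, t = 10) # 1e6 * (1e-4)^2 * 10
#' @export
driver_model <- function(p, D) {
  if (is.numeric(p)) {
    if (any(p < 0 | p > 1)) stop("driver probabilities must lie in [0, 1]",
                                 call. = FALSE)
    p_funs <- lapply(p, function(pi) function(t) rep(pi, length(t)))
  } else if (is.list(p) && all(vapply(p, is.function, logical(1)))) {
    p_funs <- p
  } else {
    stop("`p` must be a numeric vector or a list of functions", call. = FALSE)
  }
  if (is.numeric(D) && length(D) == 1) {
    if (D < 0) stop("`D` must be non-negative", call. = FALSE)
    D_fun <- local({ Dc <- D; function(t) rep(Dc, length(t)) })
  } else if (is.function(D)) {
    D_fun <- D
  } else {
    stop("`D` must be a constant or a function of time", call. = FALSE)
  }
  structure(list(p = p_funs, D = D_fun, n_drivers = length(p_funs)),
            class = "driver_model")
}

#' Evaluate the driver-probability integral
#'
#' Composite-trapezoid quadrature of `prod_i p_i(tau)` over `[0, t]` on
#' `n_grid + 1` evenly spaced nodes, multiplied by `D(t)`. Converges at
#' O(h^2) in the step size for smooth integrands; for constant `p_i = p` and
#' `D = c` the closed form is `c * p^n * t` and the quadrature is exact.
#'
#' @param model A [driver_model()].
#' @param t Time (single non-negative value, same units as the `p_i` and `D`
#'   functions).
#' @param n_grid Number of trapezoid panels (default 512).
#' @return `P(t) >= 0`.
#' @export
driver_probability <- function(model, t, n_grid = 512) {
  stopifnot(inherits(model, "driver_model"))
  if (t < 0) stop("`t` must be non-negative", call. = FALSE)
  if (t == 0) return(0)
  tau <- seq(0, t, length.out = n_grid + 1)
  integrand <- Reduce(`*`, lapply(model$p, function(f) {
    v <- f(tau)
    if (any(v < 0 | v > 1))
      stop("driver probabilities must lie in [0, 1]", call. = FALSE)
    v
  }))
  model$D(t)[1] * pracma::trapz(tau, integrand)
}

#' @export
print.driver_model <- function(x, ...) {
  cat("<driver_model>", x$n_drivers, "successive drivers\n")
  invisible(x)
}
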