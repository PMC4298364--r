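#' Grid sweep over DFE variance and mutation-rate fold increase
#'
#' Runs `replicates` seeded simulations in every cell of the
#' `sigma_grid x fold_grid` plane and records replicate-mean statistics:
#' Tier-3 accumulation slope, shape similarity of the largest-clone expansion
#' curve to the reference incidence curve, end-of-life expansion (% of pool
#' held by the top clone), and end-of-life mean fitness. Per-replicate seeds
#' are derived deterministically from `seed`, so the surface is reproducible
#' and independent of execution order.
#'
#' @param base_config A [sim_config()] providing everything except `sigma`
#'   and the rate fold.
#' @param sigma_grid Numeric vector of DFE standard deviations (the study
#'   range is log-spaced over 5e-6 to 5e-1).
#' @param fold_grid Numeric vector of lifetime mutation-rate fold increases
#'   (study range 1 to 8).
#' @param replicates Seeded replicates per grid cell (R >= 1).
#' @param ref Reference incidence curve for shape matching.
#' @param seed Seed for the replicate-seed table (defaults to the base
#'   config's seed).
#' @return An object of class `hsc_sweep`: a tibble with one row per grid
#'   cell (columns `sigma`, `fold`, `slope`, `similarity`, `expansion_pct`,
#'   `end_fitness`, `n_replicates`).
#' @export
run_grid <- function(base_config, sigma_grid, fold_grid, replicates = 3,
                     ref = default_incidence_curve(),
                     seed = base_config$seed) {
  stopifnot(inherits(base_config, "sim_config"))
  if (length(sigma_grid) == 0 || length(fold_grid) == 0)
    stop("`sigma_grid` and `fold_grid` must be non-empty", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(sigma = sigma_grid, fold = fold_grid)
  n_cells <- nrow(grid)
  set.seed(seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max, n_cells * replicates),
                     nrow = n_cells)
  cell_stats <- purrr::map(seq_len(n_cells), function(i) {
    reps <- purrr::map(seq_len(replicates), function(r) {
      cfg <- base_config
      cfg$dfe$sigma <- grid$sigma[i]
      cfg$dfe$rate_fold_increase <- grid$fold[i]
      cfg$seed <- seed_tab[i, r]
      sim <- run_simulation(cfg)
      traj <- sim$trajectory
      c(slope = tier3_slope(traj)$estimate,
        similarity = shape_similarity(sim, ref),
        expansion_pct = end_of_life_expansion(traj),
        end_fitness = traj$mean_fitness[nrow(traj)])
    })
    colMeans(do.call(rbind, reps))
  })
  stats_df <- tibble::as_tibble(do.call(rbind, cell_stats))
  out <- dplyr::bind_cols(grid, stats_df)
  out$n_replicates <- replicates
  structure(out,
            class = c("hsc_sweep", class(tibble::tibble()))) |>
    add_sweep_attrs(base_config, ref, seed, replicates)
}

add_sweep_attrs <- function(x, base_config, ref, seed, replicates) {
  attr(x, "base_config") <- base_config
  attr(x, "ref_curve") <- ref
  attr(x, "sweep_seed") <- seed
  attr(x, "replicates") <- replicates
  x
}

#' Plausible-range mask over a sweep surface
#'
#' Flags grid cells whose replicate-mean Tier-3 slope lies inside the
#' reference confidence interval (closed interval convention). The default
#' bounds are the printed AML 95% CI, 0.03759 to 0.1457 mutations/year.
#'
#' @param surface An `hsc_sweep` from [run_grid()].
#' @param ci_low,ci_high Interval bounds (mutations/year).
#' @return The surface with a logical `plausible` column added.
#' @export
plausible_mask <- function(surface, ci_low = 0.03759, ci_high = 0.1457) {
  stopifnot(inherits(surface, "hsc_sweep"))
  if (ci_low >= ci_high) stop("`ci_low` must be < `ci_high`", call. = FALSE)
  surface$plausible <- !is.na(surface$slope) &
    surface$slope >= ci_low & surface$slope <= ci_high
  surface
}

#' Shape-match mask at a stringency cutoff
#'
#' @param surface An `hsc_sweep`.
#' @param cutoff Minimum shape similarity (the study uses 0.7, 0.8, 0.9).
#' @return The surface with a logical `match` column added.
#' @export
match_mask <- function(surface, cutoff = 0.7) {
  stopifnot(inherits(surface, "hsc_sweep"))
  surface$match <- !is.na(surface$similarity) & surface$similarity >= cutoff
  surface
}

#' Overlap between the plausible range and the shape-match range
#'
#' Percentage of plausible-range grid cells whose expansion trajectory
#' reaches at least `cutoff` shape similarity to the reference incidence
#' curve: `100 * |plausible & match| / |plausible|`.
#'
#' @inheritParams match_mask
#' @param ci_low,ci_high Plausible-range slope bounds (used if the surface
#'   has no `plausible` column yet).
#' @return Percent in `[0, 100]`. An empty plausible range is an error
#'   (undefined overlap), not 0.
#' @export
overlap_percent <- function(surface, cutoff = 0.7,
                            ci_low = 0.03759, ci_high = 0.1457) {
  stopifnot(inherits(surface, "hsc_sweep"))
  if (!"plausible" %in% names(surface))
    surface <- plausible_mask(surface, ci_low, ci_high)
  n_pl <- sum(surface$plausible)
  if (n_pl == 0)
    stop("plausible range is empty: overlap is undefined", call. = FALSE)
  matched <- !is.na(surface$similarity) & surface$similarity >= cutoff
  100 * sum(surface$plausible & matched) / n_pl
}

#' @export
print.hsc_sweep <- function(x, ...) {
  cat("<hsc_sweep>", length(unique(x$sigma)), "sigma x",
      length(unique(x$fold)), "fold grid,",
      attr(x, "replicates") %||% unique(x$n_replicates),
      "replicates per cell\n")
  NextMethod()
}

#' Tidy a sweep surface into long format
#'
#' @param x An `hsc_sweep`.
#' @param ... Unused.
#' @return A tibble with columns `sigma`, `fold`, `statistic`, `value`.
#' @export
tidy.hsc_sweep <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("sigma", "fold", "slope", "similarity",
                             "expansion_pct", "end_fitness")],
    cols = c("slope", "similarity", "expansion_pct", "end_fitness"),
    names_to = "statistic", values_to = "value"
  )
}

#' One-row summary of a sweep surface
#'
#' Grid dimensions, plausible-cell count (at the default slope CI) and the
#' overlap percentages at the three stringencies used in the study.
#'
#' @param x An `hsc_sweep`.
#' @param ... Unused.
#' @export
glance.hsc_sweep <- function(x, ...) {
  m <- plausible_mask(x)
  n_pl <- sum(m$plausible)
  ov <- function(cut) {
    if (n_pl == 0) return(NA_real_)
    overlap_percent(m, cut)
  }
  tibble::tibble(
    n_cells = nrow(x),
    n_sigma = length(unique(x$sigma)),
    n_fold = length(unique(x$fold)),
    n_plausible = n_pl,
    overlap_0.7 = ov(0.7),
    overlap_0.8 = ov(0.8),
    overlap_0.9 = ov(0.9),
    max_similarity_plausible = if (n_pl > 0) max(m$similarity[m$plausible])
                               else NA_real_
  )
}
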