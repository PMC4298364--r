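#' Plot a simulation trajectory
#'
#' Faceted time-series view of the recorded trajectory: pool size, mean
#' fitness, mean Tier-3 count, largest-clone share and clone count against
#' age in years.
#'
#' @param object An `hsc_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hsc_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory,
    cols = c("pool_size", "mean_fitness", "mean_tier3",
             "top_clone_share", "n_clones"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_years, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "Age (years)", y = NULL,
                  title = "HSC pool trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a sweep surface
#'
#' Heat map of a sweep statistic over the (sigma, fold) plane, with the
#' plausible range (cells whose Tier-3 slope falls in the reference CI)
#' outlined.
#'
#' @param object An `hsc_sweep`.
#' @param statistic Column to map to fill (default `"similarity"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hsc_sweep <- function(object, statistic = "similarity", ...) {
  stopifnot(statistic %in% names(object))
  df <- plausible_mask(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = factor(.data$sigma))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[statistic]])) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$plausible),
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = statistic) +
    ggplot2::labs(x = "Mutation-rate fold increase over lifetime",
                  y = "DFE standard deviation (sigma)",
                  title = "Sweep surface (plausible range outlined)") +
    ggplot2::theme_minimal()
}

#' Plot a shape-match comparison
#'
#' Overlays the 0-1 normalized largest-clone expansion curve of a simulation
#' on the normalized reference incidence curve, annotated with the
#' similarity score.
#'
#' @param sim An `hsc_sim` or expansion-curve data frame.
#' @param ref Reference incidence curve.
#' @return A ggplot object.
#' @export
plot_shape_match <- function(sim, ref = default_incidence_curve()) {
  score <- shape_similarity(sim, ref)
  if (inherits(sim, "hsc_sim")) sim <- expansion_curve(sim)
  res <- stats::approx(sim[[1]], sim[[2]], xout = ref$age_years, rule = 2)$y
  df <- tibble::tibble(
    age_years = rep(ref$age_years, 2),
    value = c(normalize_01(res), normalize_01(ref$incidence)),
    curve = rep(c("simulated expansion", "reference incidence"),
                each = nrow(ref))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Age (years)", y = "Normalized value",
                  title = sprintf("Shape similarity = %.3f", score)) +
    ggplot2::theme_minimal()
}
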