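#' Plot transcript category counts
#'
#' Bar chart of the six-category layout from [category_counts()].
#'
#' @param de `mlx_de` tibble from [de_analysis()].
#' @param include_null Include category 0 (default FALSE).
#' @return A ggplot object.
#' @export
plot_category_counts <- function(de, include_null = FALSE) {
  counts <- category_counts(de)
  if (!include_null) counts <- counts[counts$category > 0, ]
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = factor(.data$category), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Transcript category", y = "Transcripts",
                  title = "Treatment-pattern categories") +
    ggplot2::theme_minimal()
}

#' Plot population-mean fitness by treatment
#'
#' Points per replicate population with the treatment mean and its
#' standard error overlaid.
#'
#' @param means Population-mean tibble ([population_means()]) or an
#'   `mlx_anova` with attached means.
#' @return A ggplot object.
#' @export
plot_fitness_means <- function(means) {
  if (inherits(means, "mlx_anova")) means <- attr(means, "means")
  summ <- dplyr::summarise(
    dplyr::group_by(means, .data$treatment),
    m = mean(.data$mean_value),
    se = sd(.data$mean_value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$treatment, y = .data$mean_value)) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$m, ymin = .data$m - .data$se,
                   ymax = .data$m + .data$se),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "Treatment", y = "Population mean") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation trajectory
#'
#' Allele frequency and mean fitness over generations for an
#' [run_mlx_simulation()] trajectory.
#'
#' @param object `mlx_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mlx_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("allele_freq", "mean_male_fitness", "mean_female_fitness"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Generation", y = NULL,
                  title = paste("Simulation trajectory,", object$mode[1])) +
    ggplot2::theme_minimal()
}
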