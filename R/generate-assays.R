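#' Generate a synthetic competitive-fitness vial table
#'
#' Emulates the eye-marker paternity assay: in each vial, target males
#' compete with marked competitor males and fitness is the proportion of
#' adult offspring they sire. Counts are drawn beta-binomially so vials
#' within a population can be overdispersed relative to binomial
#' sampling — the heterogeneity that motivates analysing population
#' means rather than vials. A Gaussian population effect (shared by all
#' vials of a replicate population) shifts the siring probability.
#'
#' @param treatment_props Named vector of expected siring proportions
#'   per treatment (defaults roughly 20% above/below Control for
#'   MLX/CDX).
#' @param n_populations Populations per treatment.
#' @param n_vials Vials per population (20 in the canonical protocol).
#' @param offspring_per_vial Adult offspring counted per vial.
#' @param overdispersion rho in [0, 1): beta-binomial intra-vial
#'   correlation; 0 gives pure binomial.
#' @param population_sd SD of the per-population shift on the proportion
#'   scale.
#' @param seed Integer seed.
#' @return Tibble: `treatment`, `population`, `vial_id`,
#'   `n_target_offspring`, `n_total_offspring`.
#' @examples
#' generate_fitness_assay(seed = 1)  # 180 vials
#' @export
generate_fitness_assay <- function(treatment_props =
                                     c(C = 0.5, CDX = 0.4, MLX = 0.6),
                                   n_populations = 3,
                                   n_vials = 20,
                                   offspring_per_vial = 80,
                                   overdispersion = 0.02,
                                   population_sd = 0.03,
                                   seed = NULL) {
  assert_prob(treatment_props, "treatment_props")
  assert_count(n_populations, "n_populations")
  assert_count(n_vials, "n_vials")
  assert_count(offspring_per_vial, "offspring_per_vial")
  if (overdispersion < 0 || overdispersion >= 1) {
    abort("overdispersion must be in [0, 1)")
  }
  stopifnot(population_sd >= 0)

  draw_counts(treatment_props, n_populations, n_vials, offspring_per_vial,
              overdispersion, population_sd, seed,
              count_col = "n_target_offspring",
              total_col = "n_total_offspring")
}

#' Generate a synthetic offspring sex-ratio vial table
#'
#' Same sampling scheme as [generate_fitness_assay()], but the response
#' is the number of male offspring among adults in each vial.
#'
#' @inheritParams generate_fitness_assay
#' @param treatment_props Expected proportion of male offspring per
#'   treatment.
#' @return Tibble: `treatment`, `population`, `vial_id`,
#'   `n_male_offspring`, `n_female_offspring`.
#' @export
generate_sex_ratio_assay <- function(treatment_props =
                                       c(C = 0.5, CDX = 0.45, MLX = 0.55),
                                     n_populations = 3,
                                     n_vials = 20,
                                     offspring_per_vial = 80,
                                     overdispersion = 0.02,
                                     population_sd = 0.03,
                                     seed = NULL) {
  assert_prob(treatment_props, "treatment_props")
  tab <- draw_counts(treatment_props, n_populations, n_vials,
                     offspring_per_vial, overdispersion, population_sd, seed,
                     count_col = "n_male_offspring",
                     total_col = "n_total")
  dplyr::mutate(tab,
                n_female_offspring = .data$n_total - .data$n_male_offspring,
                n_total = NULL)
}

# Shared beta-binomial vial sampler.
draw_counts <- function(props, n_populations, n_vials, n_per_vial,
                        rho, population_sd, seed, count_col, total_col) {
  with_seed_or_not(seed, {
    grid <- tidyr::expand_grid(
      treatment = factor(names(props), levels = names(props)),
      population = seq_len(n_populations)
    )
    grid$pop_shift <- rnorm(nrow(grid), 0, population_sd)
    rows <- tidyr::expand_grid(grid, vial = seq_len(n_vials))
    p_vial <- pmin(pmax(props[as.character(rows$treatment)] + rows$pop_shift,
                        0), 1)
    if (rho > 0) {
      a <- p_vial * (1 - rho) / rho
      b <- (1 - p_vial) * (1 - rho) / rho
      # beta draw undefined at p exactly 0/1; those vials are degenerate
      p_use <- ifelse(p_vial %in% c(0, 1), p_vial, rbeta(nrow(rows), a, b))
    } else {
      p_use <- p_vial
    }
    counts <- rbinom(nrow(rows), n_per_vial, p_use)
    out <- tibble::tibble(
      treatment = rows$treatment,
      population = rows$population,
      vial_id = sprintf("%s_p%d_v%02d", rows$treatment, rows$population,
                        rows$vial)
    )
    out[[count_col]] <- counts
    out[[total_col]] <- as.integer(n_per_vial)
    out
  })
}
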