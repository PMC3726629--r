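#' Per-vial proportions from a count table
#'
#' Computes the per-vial response proportion (offspring sired for the
#' fitness assay, proportion male for the sex-ratio assay). The vial is
#' the sampling unit; vials with zero total offspring carry no
#' information and are dropped with a warning reporting how many.
#'
#' @param assay Tibble with `treatment`, `population`, `vial_id`, a
#'   count column and a total column.
#' @param count_col,total_col Names of the numerator/denominator
#'   columns. For a sex-ratio table use
#'   `count_col = "n_male_offspring"` with `total_col = NULL` (total =
#'   males + females).
#' @return The assay tibble with a `proportion` column, zero-total vials
#'   removed.
#' @export
vial_proportions <- function(assay, count_col = "n_target_offspring",
                             total_col = "n_total_offspring") {
  if (is.null(total_col)) {
    stopifnot(all(c("n_male_offspring", "n_female_offspring") %in% names(assay)))
    total <- assay$n_male_offspring + assay$n_female_offspring
  } else {
    total <- assay[[total_col]]
  }
  count <- assay[[count_col]]
  if (any(count > total)) abort("count exceeds total in at least one vial")
  bad <- total == 0
  if (any(bad)) {
    warn(sprintf("dropping %d vial(s) with zero total offspring", sum(bad)))
  }
  out <- assay[!bad, , drop = FALSE]
  out$proportion <- count[!bad] / total[!bad]
  out
}

#' Population means of a per-vial response
#'
#' Averages a per-vial value to one mean per (treatment, population)
#' cell — the replication level at which treatments are compared, so
#' vials within a population are never treated as independent samples.
#'
#' @param vials Tibble with `treatment`, `population` and the response
#'   column.
#' @param value_col Response column name (default `"proportion"`).
#' @return Tibble: `treatment`, `population`, `mean_value`, `n_vials`.
#' @export
population_means <- function(vials, value_col = "proportion") {
  stopifnot(value_col %in% names(vials))
  out <- dplyr::summarise(
    dplyr::group_by(vials, .data$treatment, .data$population),
    mean_value = mean(.data[[value_col]]),
    n_vials = dplyr::n(),
    .groups = "drop"
  )
  if (any(!is.finite(out$mean_value))) {
    abort("empty or degenerate (treatment, population) cell")
  }
  out
}

#' One-way ANOVA on population means
#'
#' Omnibus treatment test at the replication level of the experiment:
#' each replicate population contributes one mean, so with 3 treatments
#' and 3 populations per treatment the test has df = (2, 6).
#'
#' @param means Tibble from [population_means()] (columns `treatment`,
#'   `population`, `mean_value`).
#' @return Object of class `mlx_anova`: list with `F`, `df1`, `df2`,
#'   `p`, `group_means`, and the underlying `lm` fit.
#' @examples
#' pm <- generate_fitness_assay(seed = 1) |>
#'   vial_proportions() |>
#'   population_means()
#' oneway_anova(pm)
#' @export
oneway_anova <- function(means) {
  stopifnot(all(c("treatment", "population", "mean_value") %in% names(means)))
  n_per <- table(means$treatment)
  n_per <- n_per[n_per > 0]
  if (length(n_per) < 2) abort("need at least 2 treatments")
  if (any(n_per < 2)) abort("need at least 2 populations per treatment")

  fit <- stats::lm(mean_value ~ treatment, data = means)
  # a perfect fit (all means equal) is legitimate input here; the
  # degenerate F is fixed up below
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  f <- unname(an[["F value"]][1])
  p <- unname(an[["Pr(>F)"]][1])
  # degenerate decompositions: treat sums of squares at floating-point
  # noise level as exact zeros
  ss_b <- an[["Sum Sq"]][1]
  ss_w <- an[["Sum Sq"]][2]
  tol <- 1e-12 * max(sum(means$mean_value^2), .Machine$double.xmin)
  if (ss_b <= tol && ss_w <= tol) {
    f <- 0; p <- 1
  } else if (ss_w <= tol) {
    f <- Inf; p <- 0
  }
  res <- structure(
    list(
      F = f,
      df1 = unname(an[["Df"]][1]),
      df2 = unname(an[["Df"]][2]),
      p = p,
      group_means = tapply(means$mean_value, means$treatment, mean),
      fit = fit
    ),
    class = "mlx_anova"
  )
  res
}

#' @export
print.mlx_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on population means: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat("Group means:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.mlx_anova <- function(x, ...) {
  tibble::tibble(
    term = names(x$group_means),
    estimate = as.numeric(x$group_means)
  )
}

#' @exportS3Method generics::glance
glance.mlx_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df1 = x$df1, df2 = x$df2, p.value = x$p)
}

#' Arcsine-square-root transform
#'
#' Variance-stabilising transform for proportions, `asin(sqrt(p))`,
#' applied to per-vial sex ratios before averaging to population means.
#'
#' @param p Proportion(s) in [0, 1].
#' @return Transformed values in radians, in [0, pi/2].
#' @export
arcsine_sqrt <- function(p) {
  assert_prob(p, "p")
  asin(sqrt(p))
}

#' Fitness or sex-ratio analysis, end to end
#'
#' Convenience wrapper: per-vial proportions, optional
#' arcsine-square-root transform (the default for sex ratios), averaging
#' to population means, then the one-way ANOVA.
#'
#' @param assay Vial count tibble.
#' @param response `"fitness"` or `"sexratio"`.
#' @param transform_at For sex ratios, `"vial"` (default: transform each
#'   vial then average) or `"population"` (average untransformed vial
#'   proportions, then transform the population means).
#' @return `mlx_anova` object; the population-mean table is attached as
#'   attribute `"means"`.
#' @export
analyze_assay <- function(assay, response = c("fitness", "sexratio"),
                          transform_at = c("vial", "population")) {
  response <- match.arg(response)
  transform_at <- match.arg(transform_at)
  if (response == "fitness") {
    vials <- vial_proportions(assay)
    pm <- population_means(vials)
  } else {
    vials <- vial_proportions(assay, count_col = "n_male_offspring",
                              total_col = NULL)
    if (transform_at == "vial") {
      vials$proportion <- arcsine_sqrt(vials$proportion)
      pm <- population_means(vials)
    } else {
      pm <- population_means(vials)
      pm$mean_value <- arcsine_sqrt(pm$mean_value)
    }
  }
  res <- oneway_anova(pm)
  attr(res, "means") <- pm
  res
}
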