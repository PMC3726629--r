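#' Generate a full-factorial array sample design
#'
#' Builds the factorial skeleton of an MLX-style expression experiment:
#' every combination of selection treatment (Control `C`, one-generation
#' paternal-X `CDX`, evolved `MLX`), replicate population, and within-
#' population replicate array. The default call reproduces the canonical
#' design of 3 treatments x 3 populations x 2 replicates = 18 arrays.
#'
#' Rows are ordered treatment-major, then population, then replicate, so
#' the same arguments always give the same table.
#'
#' @param n_treatments Number of treatments (1-3; named from `C`, `CDX`,
#'   `MLX` in that order).
#' @param n_populations Replicate populations per treatment.
#' @param n_replicates Replicate arrays per population.
#' @return A tibble with columns `sample_id`, `treatment` (factor),
#'   `population` (integer), `replicate` (integer); one row per array.
#' @examples
#' generate_design()            # the 18-array design
#' generate_design(2, 3, 4)     # 24 samples
#' @export
generate_design <- function(n_treatments = 3, n_populations = 3,
                            n_replicates = 2) {
  assert_count(n_treatments, "n_treatments")
  assert_count(n_populations, "n_populations")
  assert_count(n_replicates, "n_replicates")
  if (n_treatments > length(TREATMENTS)) {
    abort(sprintf("n_treatments must be <= %d (levels %s)",
                  length(TREATMENTS), paste(TREATMENTS, collapse = ", ")))
  }
  trt <- TREATMENTS[seq_len(n_treatments)]
  design <- tidyr::expand_grid(
    treatment = factor(trt, levels = trt),
    population = seq_len(n_populations),
    replicate = seq_len(n_replicates)
  )
  design <- dplyr::mutate(
    design,
    sample_id = sprintf("%s_p%d_r%d", .data$treatment, .data$population,
                        .data$replicate),
    .before = 1
  )
  validate_design(design)
}
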