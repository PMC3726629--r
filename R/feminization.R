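#' Cross-classify transcripts by sex-bias and CDX-shift direction
#'
#' For every informative transcript on the selected chromosome(s),
#' records whether it is female- or male-biased (external
#' `sex_bias_sign` annotation: sign of female minus male expression) and
#' whether its CDX treatment mean is above or below the Control mean.
#' All transcripts are included regardless of individual significance;
#' transcripts with an exact zero on either axis are excluded and
#' counted. If paternally inherited X chromosomes were feminized, the
#' two directions should agree more often than chance.
#'
#' @param expression Expression tibble or matrix.
#' @param design Sample design tibble.
#' @param annotation Tibble with `transcript_id`, `chromosome`,
#'   `sex_bias_sign`.
#' @param chromosome `"X"`, `"autosomes"`, or a character vector of
#'   chromosome names to keep.
#' @return List of class `mlx_directions`: `counts` (tibble with the
#'   four cells), `observed` (named numeric, cells ordered female-up/
#'   CDX-up, female-up/CDX-down, female-down/CDX-up,
#'   female-down/CDX-down), `n_excluded_zero`, `n_considered`.
#' @export
classify_directions <- function(expression, design, annotation,
                                chromosome = "X") {
  values <- if (is.matrix(expression)) expression else
    expression_matrix(expression)
  validate_design(design)
  keep_chroms <- if (identical(chromosome, "autosomes")) {
    setdiff(unique(annotation$chromosome), "X")
  } else chromosome

  ann <- annotation[annotation$chromosome %in% keep_chroms, , drop = FALSE]
  ids <- intersect(rownames(values), ann$transcript_id)
  if (length(ids) == 0) abort("no transcripts on the selected chromosome(s)")
  if (any(is.na(ann$sex_bias_sign))) {
    abort("sex_bias_sign must be available for every transcript considered")
  }

  sub <- values[ids, , drop = FALSE]
  is_c <- design$treatment == "C"
  is_cdx <- design$treatment == "CDX"
  cdx_shift <- rowMeans(sub[, is_cdx, drop = FALSE]) -
    rowMeans(sub[, is_c, drop = FALSE])
  bias <- stats::setNames(ann$sex_bias_sign, ann$transcript_id)[ids]

  informative <- bias != 0 & cdx_shift != 0
  n_excluded <- sum(!informative)
  b <- bias[informative]
  s <- sign(cdx_shift[informative])

  observed <- c(
    "female_up.cdx_up" = sum(b > 0 & s > 0),
    "female_up.cdx_down" = sum(b > 0 & s < 0),
    "female_down.cdx_up" = sum(b < 0 & s > 0),
    "female_down.cdx_down" = sum(b < 0 & s < 0)
  )
  counts <- tibble::tibble(
    sex_bias = rep(c("female_biased", "male_biased"), each = 2),
    cdx_direction = rep(c("up_in_CDX", "down_in_CDX"), 2),
    n = as.integer(observed)
  )
  structure(
    list(counts = counts, observed = observed,
         n_excluded_zero = n_excluded, n_considered = length(ids)),
    class = "mlx_directions"
  )
}

#' @export
print.mlx_directions <- function(x, ...) {
  cat(sprintf("Direction cross-classification (%d transcripts, %d excluded):\n",
              x$n_considered, x$n_excluded_zero))
  print(x$counts)
  invisible(x)
}

#' Chi-square test of the four-cell direction table
#'
#' Omnibus test of the direction cross-classification against a uniform
#' null: each of the four cells expects total/4 of the informative
#' transcripts, so chi2 = sum (O - E)^2 / E with df = 3. Note this is a
#' uniform null over cells, not an independence (margin-product) null;
#' it asks whether transcripts spread evenly over the four
#' direction combinations. Feminization specifically would concentrate
#' mass in the concordant cells (female-up/CDX-up and
#' female-down/CDX-down), so the concordant fraction is reported
#' alongside the omnibus statistic.
#'
#' @param counts `mlx_directions` object, or a numeric vector of four
#'   cell counts ordered (female-up/CDX-up, female-up/CDX-down,
#'   female-down/CDX-up, female-down/CDX-down).
#' @return List of class `mlx_chisq` with `observed`, `expected`,
#'   `statistic`, `df`, `p`, `concordant_fraction`, `table`.
#' @examples
#' feminization_chisq(c(116, 69, 187, 71))
#' @export
feminization_chisq <- function(counts) {
  observed <- if (inherits(counts, "mlx_directions")) counts$observed
              else as.numeric(counts)
  if (length(observed) != 4 || any(observed < 0)) {
    abort("need four non-negative cell counts")
  }
  total <- sum(observed)
  if (total == 0) abort("no informative transcripts: all cells are zero")
  expected <- rep(total / 4, 4)
  stat <- sum((observed - expected)^2 / expected)
  cells <- c("female_up.cdx_up", "female_up.cdx_down",
             "female_down.cdx_up", "female_down.cdx_down")
  structure(
    list(observed = stats::setNames(observed, cells),
         expected = stats::setNames(expected, cells),
         statistic = stat, df = 3L,
         p = pchisq(stat, 3, lower.tail = FALSE),
         concordant_fraction = (observed[1] + observed[4]) / total,
         table = tibble::tibble(cell = cells, observed = observed,
                                expected = expected)),
    class = "mlx_chisq"
  )
}

#' Feminization direction test, end to end
#'
#' [classify_directions()] followed by [feminization_chisq()].
#'
#' @inheritParams classify_directions
#' @return `mlx_chisq` object with the direction counts attached as
#'   attribute `"directions"`.
#' @export
feminization_test <- function(expression, design, annotation,
                              chromosome = "X") {
  dirs <- classify_directions(expression, design, annotation, chromosome)
  res <- feminization_chisq(dirs)
  attr(res, "directions") <- dirs
  res
}
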