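#' Hypergeometric GO over-representation test
#'
#' For each GO term, tests whether the gene set contains more members of
#' the term than expected under sampling without replacement from the
#' universe: upper-tail hypergeometric p = P(X >= observed), with the
#' universe as the population, the term's universe members as successes
#' and the set size as the number of draws. Annotations are used flat
#' (no graph propagation); p-values are reported raw by default, with
#' BH adjustment available.
#'
#' @param gene_set Character vector of transcript ids (subset of
#'   `universe`).
#' @param universe Character vector of all informative transcript ids.
#' @param go_map Tibble with columns `transcript_id`, `term_id`, or an
#'   annotation tibble from [generate_annotations()] (its `go_terms`
#'   list-column is unnested).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble, one row per term present in the universe: `term_id`,
#'   `term_size`, `observed`, `expected`, `p_raw`, `p_adjusted`.
#' @export
hypergeom_go <- function(gene_set, universe, go_map,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_in_universe(gene_set, universe)
  go_map <- as_go_map(go_map)
  go_map <- go_map[go_map$transcript_id %in% universe, , drop = FALSE]

  n_universe <- length(unique(universe))
  n_draws <- length(unique(gene_set))
  per_term <- dplyr::summarise(
    dplyr::group_by(go_map, .data$term_id),
    term_size = dplyr::n_distinct(.data$transcript_id),
    observed = sum(unique(.data$transcript_id) %in% gene_set),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    per_term,
    expected = n_draws * .data$term_size / n_universe,
    p_raw = phyper(.data$observed - 1, .data$term_size,
                   n_universe - .data$term_size, n_draws,
                   lower.tail = FALSE)
  )
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_raw, "BH") else NA_real_
  dplyr::arrange(out, .data$p_raw)
}

as_go_map <- function(go_map) {
  if ("go_terms" %in% names(go_map)) {
    go_map <- tidyr::unnest(
      dplyr::select(go_map, "transcript_id", "go_terms"),
      "go_terms"
    )
    names(go_map)[names(go_map) == "go_terms"] <- "term_id"
  }
  stopifnot(all(c("transcript_id", "term_id") %in% names(go_map)))
  go_map
}

check_in_universe <- function(gene_set, universe) {
  off <- setdiff(gene_set, universe)
  if (length(off) > 0) {
    abort(paste0("gene_set members not in universe: ",
                 paste(utils::head(off, 5), collapse = ", "),
                 if (length(off) > 5) sprintf(" (+%d more)", length(off) - 5)))
  }
}

#' Chi-square test of chromosomal distribution
#'
#' Compares the observed chromosome-arm counts of a gene set with the
#' counts expected from the universe's chromosome proportions:
#' chi2 = sum (O - E)^2 / E with df = #chromosomes - 1. Chromosomes can
#' be excluded (e.g. the gene-poor chromosome 4); proportions are then
#' recomputed over the remaining chromosomes and set members on excluded
#' chromosomes are dropped. Cells with expected count 0 are removed with
#' a warning, reducing df.
#'
#' @param gene_set Transcript ids.
#' @param annotation Tibble with `transcript_id`, `chromosome`.
#' @param universe Transcript ids forming the reference distribution.
#' @param exclude_chromosomes Chromosomes to drop before testing.
#' @return List of class `mlx_chisq`: `observed`, `expected`,
#'   `statistic`, `df`, `p`, `table` (tibble).
#' @export
chrom_chisq <- function(gene_set, annotation, universe,
                        exclude_chromosomes = character()) {
  check_in_universe(gene_set, universe)
  chrom <- stats::setNames(annotation$chromosome, annotation$transcript_id)
  if (any(is.na(chrom[universe]))) {
    abort("every universe transcript must have a chromosome annotation")
  }
  keep <- !(chrom[universe] %in% exclude_chromosomes)
  uni_chrom <- chrom[universe][keep]
  set_chrom <- chrom[gene_set]
  set_chrom <- set_chrom[!(set_chrom %in% exclude_chromosomes)]

  chroms <- sort(unique(uni_chrom))
  observed <- as.numeric(table(factor(set_chrom, levels = chroms)))
  props <- as.numeric(table(factor(uni_chrom, levels = chroms))) /
    length(uni_chrom)
  expected <- length(set_chrom) * props

  drop <- expected == 0
  if (any(drop)) {
    warn(sprintf("dropping %d chromosome cell(s) with expected count 0",
                 sum(drop)))
    chroms <- chroms[!drop]; observed <- observed[!drop]
    expected <- expected[!drop]
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(chroms) - 1L
  structure(
    list(observed = stats::setNames(observed, chroms),
         expected = stats::setNames(expected, chroms),
         statistic = stat, df = df,
         p = pchisq(stat, df, lower.tail = FALSE),
         table = tibble::tibble(chromosome = chroms, observed = observed,
                                expected = expected)),
    class = "mlx_chisq"
  )
}

#' @export
print.mlx_chisq <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mlx_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p)
}

#' One-tailed Fisher tests of tissue-specific enrichment
#'
#' For each tissue, builds the 2 x 2 table (in gene set vs not) x
#' (tissue-specific vs not) over the universe and tests enrichment with
#' a one-tailed Fisher exact test (`alternative = "greater"`). P-values
#' are Bonferroni-corrected for the number of tissues tested (17 for the
#' full atlas panel).
#'
#' @param gene_set Transcript ids.
#' @param tissue_sets Named list of character vectors (tissue ->
#'   tissue-specific transcripts), or an annotation tibble with a
#'   `tissue_specific_in` list-column.
#' @param universe Transcript ids.
#' @param strict_panel Require exactly 17 tissues.
#' @return Tibble: `tissue`, `n_specific`, `observed`, `expected`,
#'   `odds_ratio`, `p_raw`, `p_adjusted` (= min(1, n_tissues * p_raw)).
#' @export
tissue_fisher <- function(gene_set, tissue_sets, universe,
                          strict_panel = FALSE) {
  check_in_universe(gene_set, universe)
  tissue_sets <- as_tissue_sets(tissue_sets)
  if (strict_panel && length(tissue_sets) != 17) {
    abort("canonical-protocol tissue panel must have exactly 17 tissues")
  }
  for (tis in names(tissue_sets)) {
    off <- setdiff(tissue_sets[[tis]], universe)
    if (length(off) > 0) {
      abort(sprintf("tissue set '%s' has members outside the universe", tis))
    }
  }
  n_tissues <- length(tissue_sets)
  n_uni <- length(unique(universe))
  n_set <- length(unique(gene_set))

  purrr::map_dfr(names(tissue_sets), function(tis) {
    specific <- unique(tissue_sets[[tis]])
    a <- sum(gene_set %in% specific)
    tab <- matrix(c(a, n_set - a,
                    length(specific) - a,
                    n_uni - n_set - (length(specific) - a)), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    or <- suppressWarnings(fisher.test(tab)$estimate)
    tibble::tibble(
      tissue = tis,
      n_specific = length(specific),
      observed = a,
      expected = n_set * length(specific) / n_uni,
      odds_ratio = unname(or),
      p_raw = p,
      p_adjusted = pmin(1, n_tissues * p)
    )
  }) |>
    dplyr::arrange(.data$p_raw)
}

as_tissue_sets <- function(tissue_sets) {
  if (is.data.frame(tissue_sets) && "tissue_specific_in" %in% names(tissue_sets)) {
    long <- tidyr::unnest(
      dplyr::select(tissue_sets, "transcript_id", "tissue_specific_in"),
      "tissue_specific_in"
    )
    return(split(long$transcript_id, long$tissue_specific_in))
  }
  stopifnot(is.list(tissue_sets), !is.null(names(tissue_sets)))
  tissue_sets
}

#' Two-tailed mean-rank gene set enrichment (MR-GSE)
#'
#' Tests whether a gene set's mean rank in a genome-wide association
#' ranking (rank 1 = strongest association) deviates from its null
#' expectation under random sampling without replacement. The statistic
#' is the set's mean rank; under the null its mean is (N + 1)/2 and its
#' variance (N - n)(N + 1)/(12 n) for set size n out of N ranked
#' transcripts. `method = "normal"` uses the z approximation;
#' `method = "exact"` uses the exact rank-sum permutation distribution
#' (valid in the absence of ties, feasible for n * N up to ~1e5).
#'
#' @param gene_set Transcript ids.
#' @param ranking Named numeric vector of scores (names = transcript
#'   ids; larger score = stronger association), or a tibble with columns
#'   `transcript_id` and `score` or `rank`. Scores are converted to
#'   ranks with ties mid-ranked.
#' @param method `"normal"`, `"exact"`, or `"auto"` (exact when
#'   n * N <= 1e5).
#' @return List of class `mlx_mrgse`: `mean_rank`, `null_mean`,
#'   `null_sd`, `z`, `p`, `n_set`, `n_universe`, `method`.
#' @export
mr_gse <- function(gene_set, ranking, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  ranks <- as_ranking(ranking)
  off <- setdiff(gene_set, names(ranks))
  if (length(off) > 0) abort("gene_set members missing from ranking")
  n_total <- length(ranks)
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  if (n < 1) abort("gene_set must be non-empty")
  if (n >= n_total) abort("gene_set must be a strict subset of the ranking")

  mean_rank <- mean(ranks[gene_set])
  null_mean <- (n_total + 1) / 2
  null_var <- (n_total - n) * (n_total + 1) / (12 * n)
  z <- (mean_rank - null_mean) / sqrt(null_var)

  if (method == "auto") {
    # exact distribution cost grows with n * (N - n); beyond this the
    # normal approximation is already accurate to ~1e-2
    method <- if (n * (n_total - n) <= 1e4) "exact" else "normal"
  }
  if (method == "exact") {
    # rank sum W = n * mean_rank; U = W - n(n+1)/2 is Wilcoxon rank-sum
    # distributed over the subsets of size n (no ties assumed)
    u <- round(n * mean_rank - n * (n + 1) / 2)
    m_other <- n_total - n
    eu <- n * m_other / 2
    dev <- abs(u - eu)
    lo <- eu - dev
    hi <- eu + dev
    p <- pwilcox(lo, n, m_other) +
      pwilcox(hi - 1, n, m_other, lower.tail = FALSE)
    p <- min(1, p)
  } else {
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  structure(
    list(mean_rank = mean_rank, null_mean = null_mean,
         null_sd = sqrt(null_var), z = z, p = p,
         n_set = n, n_universe = n_total, method = method),
    class = "mlx_mrgse"
  )
}

as_ranking <- function(ranking) {
  if (is.data.frame(ranking)) {
    stopifnot("transcript_id" %in% names(ranking))
    if ("rank" %in% names(ranking)) {
      return(stats::setNames(as.numeric(ranking$rank), ranking$transcript_id))
    }
    stopifnot("score" %in% names(ranking))
    sc <- stats::setNames(ranking$score, ranking$transcript_id)
  } else {
    stopifnot(is.numeric(ranking), !is.null(names(ranking)))
    sc <- ranking
  }
  # rank 1 = strongest association = largest score; ties mid-ranked
  rank(-sc, ties.method = "average")
}

#' @export
print.mlx_mrgse <- function(x, ...) {
  cat(sprintf(paste0("MR-GSE: mean rank %.2f of %d (set n = %d), ",
                     "z = %.3f, two-tailed p = %.4g [%s]\n"),
              x$mean_rank, x$n_universe, x$n_set, x$z, x$p, x$method))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mlx_mrgse <- function(x, ...) {
  tibble::tibble(mean_rank = x$mean_rank, z = x$z, p.value = x$p,
                 n_set = x$n_set, n_universe = x$n_universe,
                 method = x$method)
}
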