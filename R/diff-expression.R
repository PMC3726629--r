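#' Nested ANOVA for one transcript
#'
#' Tests for a treatment effect with Treatment as a fixed factor and
#' Population as a random factor nested within Treatment. Under this
#' model the correct error term for Treatment is the
#' population-within-treatment mean square, so with t treatments and b
#' populations per treatment the test has df1 = t - 1 and
#' df2 = t(b - 1) regardless of how many replicate arrays each
#' population contributes — for the 3 x 3 x 2 design, df = (2, 6).
#'
#' Only balanced designs (equal replicates per population, equal
#' populations per treatment) are accepted.
#'
#' @param values Numeric vector, one value per design row.
#' @param design Sample design tibble ([generate_design()]).
#' @return List: `F`, `df1`, `df2`, `p`, `treatment_means` (named).
#' @examples
#' d <- generate_design()
#' nested_anova(rnorm(18), d)
#' @export
nested_anova <- function(values, design) {
  m <- matrix(as.numeric(values), nrow = 1)
  res <- nested_anova_matrix(m, design)
  list(F = res$F[1], df1 = res$df1, df2 = res$df2, p = res$p[1],
       treatment_means = res$treatment_means[1, ])
}

# Vectorised nested ANOVA across the rows of an expression matrix.
# Returns per-row F/p plus the mean squares needed by the contrasts.
nested_anova_matrix <- function(values, design) {
  validate_design(design)
  stopifnot(ncol(values) == nrow(design))
  trt <- droplevels(as.factor(design$treatment))
  cell <- interaction(trt, design$population, drop = TRUE)

  r_per_cell <- table(cell)
  b_per_trt <- table(trt) / r_per_cell[1]
  if (length(unique(r_per_cell)) != 1 || length(unique(b_per_trt)) != 1) {
    abort("nested ANOVA requires a balanced design")
  }
  t_n <- nlevels(trt)
  b <- as.integer(b_per_trt[1])
  r <- as.integer(r_per_cell[1])
  if (t_n < 2) abort("need at least 2 treatments")
  if (b < 2) abort("need at least 2 populations per treatment")

  # group-mean operators (columns sum to 1 within a group)
  Mt <- stats::model.matrix(~ trt - 1)
  Mt <- sweep(Mt, 2, colSums(Mt), "/")
  Mc <- stats::model.matrix(~ cell - 1)
  Mc <- sweep(Mc, 2, colSums(Mc), "/")

  trt_means <- values %*% Mt                 # n x t
  cell_means <- values %*% Mc                # n x (t*b)
  grand <- rowMeans(values)

  cell_trt <- trt[match(levels(cell), cell)] # treatment of each cell
  ss_t <- b * r * rowSums((trt_means - grand)^2)
  ss_p <- r * rowSums((cell_means - trt_means[, as.integer(cell_trt),
                                              drop = FALSE])^2)
  df1 <- t_n - 1L
  df2 <- t_n * (b - 1L)
  ms_t <- ss_t / df1
  ms_p <- ss_p / df2
  f <- ifelse(ms_p > 0, ms_t / ms_p, ifelse(ms_t > 0, Inf, 0))
  p <- ifelse(is.finite(f), pf(f, df1, df2, lower.tail = FALSE),
              ifelse(f > 0, 0, 1))
  p[f == 0] <- 1

  colnames(trt_means) <- levels(trt)
  list(F = f, df1 = df1, df2 = df2, p = p,
       treatment_means = trt_means, ms_p = ms_p,
       n_per_treatment = b * r)
}

#' Pairwise treatment contrasts for one transcript
#'
#' Tests each pair of treatment means using the population-within-
#' treatment mean square as the error term (with its df, 6 in the
#' canonical design). The difference is reported as second minus first
#' on the log2 scale, for the pairs C-CDX, C-MLX, CDX-MLX.
#'
#' @inheritParams nested_anova
#' @return Tibble: `contrast`, `difference`, `statistic`, `p`.
#' @export
pairwise_contrasts <- function(values, design) {
  m <- matrix(as.numeric(values), nrow = 1)
  fit <- nested_anova_matrix(m, design)
  pc <- pairwise_contrasts_matrix(fit)
  tibble::tibble(
    contrast = colnames(pc$difference),
    difference = pc$difference[1, ],
    statistic = pc$statistic[1, ],
    p = pc$p[1, ]
  )
}

pairwise_contrasts_matrix <- function(fit) {
  lv <- colnames(fit$treatment_means)
  pairs <- utils::combn(lv, 2)
  lab <- apply(pairs, 2, paste, collapse = "-")
  n <- fit$n_per_treatment
  se <- sqrt(fit$ms_p * 2 / n)               # per-row SE of a mean diff
  diffs <- sapply(seq_len(ncol(pairs)), function(k) {
    fit$treatment_means[, pairs[2, k]] - fit$treatment_means[, pairs[1, k]]
  })
  diffs <- matrix(diffs, ncol = ncol(pairs), dimnames = list(NULL, lab))
  tstat <- diffs / se
  tstat[se == 0 & diffs == 0] <- 0
  pval <- 2 * pt(abs(tstat), fit$df2, lower.tail = FALSE)
  pval[!is.finite(tstat)] <- 0
  list(difference = diffs, statistic = tstat, p = pval)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q_star`: reject all hypotheses with
#' p <= p_(k) where k is the largest i with p_(i) <= i q*/m.
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param q_star Target FDR (default 0.05).
#' @return List: `qvals` (BH-adjusted p-values), `reject` (logical).
#' @export
bh_fdr <- function(pvals, q_star = 0.05) {
  if (length(pvals) == 0) return(list(qvals = numeric(), reject = logical()))
  assert_prob(pvals, "pvals")
  q <- p.adjust(pvals, method = "BH")
  list(qvals = q, reject = q <= q_star)
}

#' Classify a transcript's treatment pattern
#'
#' Assigns one of the six treatment-pattern categories from the pairwise
#' significance flags and treatment means:
#'
#' * 1 — CDX and MLX both differ from C, in the same direction, and not
#'   from each other (maternal effect).
#' * 2 — CDX differs from both C and MLX, which do not differ
#'   (imprinting signature).
#' * 3 — MLX differs from both C and CDX, which do not differ (MLX
#'   evolution).
#' * 4/5/6 — all three pairs differ; the middle mean decides the order:
#'   C in the middle = 4 (CDX-C-MLX, fitness-related), MLX = 5
#'   (CDX-MLX-C), CDX = 6 (C-CDX-MLX).
#' * 0 — anything else (no pair, a single pair, or CDX/MLX deviating
#'   from C in opposite directions), with the reason recorded.
#'
#' In `mode = "lenient"`, an ordered category (4-6) is accepted already
#' when CDX-MLX plus at least one other pair is significant; this trades
#' specificity against categories 2/3 for sensitivity to ordered
#' patterns and is reported for comparison only.
#'
#' `direction` is `"up"` when the means increase along the category's
#' stated order (for 1-3: when the deviating group is above C).
#'
#' @param sig Named logical vector with elements `"C-CDX"`, `"C-MLX"`,
#'   `"CDX-MLX"`.
#' @param treatment_means Named numeric vector with elements `C`, `CDX`,
#'   `MLX`.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return List: `category` (0-6), `direction` (`"up"`, `"down"` or
#'   `NA`), `reason` (why category 0, else `NA`).
#' @export
classify_category <- function(sig, treatment_means,
                              mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  need <- c("C-CDX", "C-MLX", "CDX-MLX")
  stopifnot(all(need %in% names(sig)),
            all(c("C", "CDX", "MLX") %in% names(treatment_means)))
  s_ccdx <- isTRUE(sig[["C-CDX"]])
  s_cmlx <- isTRUE(sig[["C-MLX"]])
  s_dxmlx <- isTRUE(sig[["CDX-MLX"]])
  m <- treatment_means

  none <- list(category = 0L, direction = NA_character_, reason = NA_character_)

  ordered_cat <- function() {
    mid <- names(m)[order(m)][2]
    cat_id <- c(C = 4L, MLX = 5L, CDX = 6L)[[mid]]
    stated <- list(`4` = c("CDX", "C", "MLX"),
                   `5` = c("CDX", "MLX", "C"),
                   `6` = c("C", "CDX", "MLX"))[[as.character(cat_id)]]
    dir <- if (m[[stated[3]]] > m[[stated[1]]]) "up" else "down"
    list(category = cat_id, direction = dir, reason = NA_character_)
  }

  nsig <- s_ccdx + s_cmlx + s_dxmlx
  if (nsig == 0) {
    none$reason <- "no significant pair"
    return(none)
  }
  if (nsig == 3) {
    if (anyDuplicated(m)) {
      none$reason <- "tied means with all pairs significant"
      return(none)
    }
    return(ordered_cat())
  }
  if (mode == "lenient" && s_dxmlx && nsig == 2 && !anyDuplicated(m)) {
    return(ordered_cat())
  }
  if (nsig == 1) {
    none$reason <- "single significant pair"
    return(none)
  }
  # exactly two significant pairs
  if (s_ccdx && s_cmlx) {
    d_cdx <- m[["CDX"]] - m[["C"]]
    d_mlx <- m[["MLX"]] - m[["C"]]
    if (sign(d_cdx) == sign(d_mlx) && d_cdx != 0) {
      return(list(category = 1L,
                  direction = if (d_cdx > 0) "up" else "down",
                  reason = NA_character_))
    }
    none$reason <- "CDX and MLX deviate from C in opposite directions"
    return(none)
  }
  if (s_ccdx && s_dxmlx) {
    d <- m[["CDX"]] - m[["C"]]
    return(list(category = 2L, direction = if (d > 0) "up" else "down",
                reason = NA_character_))
  }
  # s_cmlx && s_dxmlx
  d <- m[["MLX"]] - m[["C"]]
  list(category = 3L, direction = if (d > 0) "up" else "down",
      reason = NA_character_)
}

#' Differential-expression analysis of an expression matrix
#'
#' Runs the per-transcript nested ANOVA across all transcripts, controls
#' the FDR over the overall tests with Benjamini-Hochberg at `q_star`,
#' evaluates the three pairwise contrasts for transcripts passing the
#' FDR gate (at unadjusted `pairwise_alpha` by default, or BH-adjusted
#' across all gated pairwise tests with
#' `pairwise_adjust = "BH"`), and assigns each transcript a
#' treatment-pattern category.
#'
#' @param expression Expression tibble (`transcript_id` + sample
#'   columns) or numeric matrix with transcript rownames.
#' @param design Sample design tibble.
#' @param q_star FDR level for the overall tests.
#' @param pairwise_alpha Significance level for gated pairwise tests.
#' @param pairwise_adjust `"none"` (default) or `"BH"` across all
#'   pairwise tests of FDR-passing transcripts.
#' @param mode Category mode, `"strict"` or `"lenient"`.
#' @return Tibble of class `mlx_de`, one row per transcript:
#'   `transcript_id`, `overall_F`, `overall_p`, `overall_q`, `mean_C`,
#'   `mean_CDX`, `mean_MLX`, per-contrast `diff_*` / `p_*` / `sig_*`,
#'   `category`, `direction`, `reason`.
#' @examples
#' sim <- generate_expression(generate_design(), 200, c("4" = 0.05),
#'                            seed = 1)
#' de <- de_analysis(sim$expression, sim$design)
#' dplyr::count(de, category)
#' @export
de_analysis <- function(expression, design, q_star = 0.05,
                        pairwise_alpha = 0.05,
                        pairwise_adjust = c("none", "BH"),
                        mode = c("strict", "lenient")) {
  pairwise_adjust <- match.arg(pairwise_adjust)
  mode <- match.arg(mode)
  values <- if (is.matrix(expression)) expression else
    expression_matrix(expression)

  fit <- nested_anova_matrix(values, design)
  fdr <- bh_fdr(fit$p, q_star)
  pc <- pairwise_contrasts_matrix(fit)

  gate <- fdr$reject
  sig <- matrix(FALSE, nrow(values), 3,
                dimnames = list(NULL, colnames(pc$p)))
  if (any(gate)) {
    p_gated <- pc$p[gate, , drop = FALSE]
    if (pairwise_adjust == "BH") {
      adj <- matrix(p.adjust(p_gated, method = "BH"), nrow = sum(gate))
      sig[gate, ] <- adj <= pairwise_alpha
    } else {
      sig[gate, ] <- p_gated <= pairwise_alpha
    }
  }

  cls <- lapply(seq_len(nrow(values)), function(i) {
    if (!gate[i]) {
      return(list(category = 0L, direction = NA_character_,
                  reason = "did not pass FDR"))
    }
    classify_category(sig[i, ], fit$treatment_means[i, ], mode = mode)
  })

  out <- tibble::tibble(
    transcript_id = rownames(values),
    overall_F = fit$F,
    overall_p = fit$p,
    overall_q = fdr$qvals,
    mean_C = fit$treatment_means[, "C"],
    mean_CDX = fit$treatment_means[, "CDX"],
    mean_MLX = fit$treatment_means[, "MLX"],
    diff_C_CDX = pc$difference[, "C-CDX"],
    p_C_CDX = pc$p[, "C-CDX"],
    sig_C_CDX = sig[, "C-CDX"],
    diff_C_MLX = pc$difference[, "C-MLX"],
    p_C_MLX = pc$p[, "C-MLX"],
    sig_C_MLX = sig[, "C-MLX"],
    diff_CDX_MLX = pc$difference[, "CDX-MLX"],
    p_CDX_MLX = pc$p[, "CDX-MLX"],
    sig_CDX_MLX = sig[, "CDX-MLX"],
    category = vapply(cls, `[[`, integer(1), "category"),
    direction = vapply(cls, `[[`, character(1), "direction"),
    reason = vapply(cls, `[[`, character(1), "reason")
  )
  class(out) <- c("mlx_de", class(out))
  attr(out, "df") <- c(df1 = fit$df1, df2 = fit$df2)
  attr(out, "q_star") <- q_star
  out
}

#' @exportS3Method generics::glance
glance.mlx_de <- function(x, ...) {
  df <- attr(x, "df")
  tibble::tibble(
    n_transcripts = nrow(x),
    n_significant = sum(x$overall_q <= attr(x, "q_star")),
    n_classified = sum(x$category > 0),
    df1 = df[["df1"]],
    df2 = df[["df2"]]
  )
}

#' Category count summary in the six-category layout
#'
#' @param de `mlx_de` tibble from [de_analysis()].
#' @return Tibble: `category` (0-6), `label`, `n`.
#' @export
category_counts <- function(de) {
  labels <- c("unclassified / null", "maternal effect", "imprinting (CDX only)",
              "MLX evolution", "fitness (CDX-C-MLX)",
              "reduced maternal effect (CDX-MLX-C)",
              "enhanced maternal effect (C-CDX-MLX)")
  tibble::tibble(category = 0:6, label = labels) |>
    dplyr::left_join(dplyr::count(tibble::as_tibble(de), .data$category),
                     by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
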