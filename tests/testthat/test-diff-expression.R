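test_that("nested ANOVA has the design-determined degrees of freedom", {
  d <- generate_design()
  res <- nested_anova(rnorm(18), d)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)

  # all values equal -> F = 0, p = 1
  flat <- nested_anova(rep(3.7, 18), d)
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)

  # unbalanced data is rejected
  expect_error(nested_anova(rnorm(17), d[-1, ]), "balanced")
})

test_that("nested ANOVA agrees with the linear-model oracle", {
  d <- generate_design()
  # hand-constructed: population means (0,0,0)/(1,1,1)/(2,2,2), zero residual
  y <- rep(c(0, 1, 2), each = 6)
  res <- nested_anova(y, d)
  ora <- suppressWarnings(oracle_nested_anova(y, d))  # perfect-fit warning
  # MS_pop = 0 here: both routes must agree the F blows up
  expect_true(is.infinite(res$F) || res$F > 1e12)
  expect_true(is.infinite(ora$F) || is.nan(ora$F) || ora$F > 1e12)

  # and on noisy data they match to floating-point accuracy
  withr::local_seed(11)
  for (i in 1:100) {
    y <- rnorm(18, mean = rep(rnorm(3, sd = runif(1, 0, 2)), each = 6))
    res <- nested_anova(y, d)
    ora <- oracle_nested_anova(y, d)
    expect_equal(res$F, ora$F, tolerance = 1e-8)
    expect_equal(res$p, ora$p, tolerance = 1e-8)
    expect_equal(res$df1, ora$df1)
    expect_equal(res$df2, ora$df2)
  }
})

test_that("oracle agreement holds across design shapes", {
  withr::local_seed(12)
  for (shape in list(c(2, 2, 2), c(3, 4, 3), c(2, 3, 5))) {
    d <- generate_design(shape[1], shape[2], shape[3])
    y <- rnorm(nrow(d))
    res <- nested_anova(y, d)
    ora <- oracle_nested_anova(y, d)
    expect_equal(res$F, ora$F, tolerance = 1e-8)
    expect_equal(res$df2, ora$df2)
  }
})

test_that("pairwise contrasts use the population mean square as error term", {
  d <- generate_design()
  withr::local_seed(13)
  # symmetric data with C = MLX exactly
  base <- rnorm(6)
  y <- c(base, rnorm(6, 2), base)
  pc <- pairwise_contrasts(y, d)
  expect_equal(unname(pc$difference[pc$contrast == "C-MLX"]), 0)
  expect_equal(unname(pc$p[pc$contrast == "C-MLX"]), 1)

  # squared contrast t (with the 2-group error term) equals the
  # 2-group nested ANOVA F
  y2 <- rnorm(18, rep(c(0, 1, 0.3), each = 6))
  sub <- d$treatment %in% c("C", "CDX")
  d_sub <- d[sub, ]
  d_sub$treatment <- droplevels(d_sub$treatment)
  fit2 <- mlxtools:::nested_anova_matrix(matrix(y2[sub], 1), d_sub)
  diff2 <- fit2$treatment_means[1, "CDX"] - fit2$treatment_means[1, "C"]
  t2 <- diff2 / sqrt(fit2$ms_p[1] * 2 / fit2$n_per_treatment)
  expect_equal(unname(t2^2), fit2$F[1], tolerance = 1e-10)
})

test_that("planted CDX-only transcripts yield the category-2 contrast pattern", {
  d <- generate_design()
  sim <- generate_expression(d, 60, c("2" = 0.5), effect_size = 3,
                             population_sd = 0.05, residual_sd = 0.3,
                             seed = 14)
  m <- expression_matrix(sim$expression)
  planted <- which(sim$truth$planted_category == 2)
  hits <- vapply(planted, function(i) {
    pc <- pairwise_contrasts(m[i, ], d)
    sig <- pc$p <= 0.05
    names(sig) <- pc$contrast
    sig[["C-CDX"]] && sig[["CDX-MLX"]] && !sig[["C-MLX"]]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("BH step-up matches the hand-worked examples", {
  expect_equal(sum(bh_fdr(rep(1, 10), 0.05)$reject), 0)
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)$reject))
  r <- bh_fdr(c(0.001, 0.3, 0.9), 0.05)
  expect_equal(sum(r$reject), 1)
  expect_true(r$reject[1])
  expect_true(all(r$qvals >= c(0.001, 0.3, 0.9)))  # q >= p always
  empty <- bh_fdr(numeric(0))
  expect_length(empty$qvals, 0)
})

test_that("category classifier implements the six-pattern mapping", {
  mk_sig <- function(ccdx, cmlx, dxmlx) {
    c("C-CDX" = ccdx, "C-MLX" = cmlx, "CDX-MLX" = dxmlx)
  }
  means_up4 <- c(C = 0, CDX = -1, MLX = 1)

  # all three significant, CDX < C < MLX -> category 4
  r <- classify_category(mk_sig(TRUE, TRUE, TRUE), means_up4)
  expect_equal(r$category, 4L)
  expect_equal(r$direction, "up")

  # middle = MLX -> 5; middle = CDX -> 6
  expect_equal(classify_category(mk_sig(TRUE, TRUE, TRUE),
                                 c(C = 1, CDX = -1, MLX = 0))$category, 5L)
  expect_equal(classify_category(mk_sig(TRUE, TRUE, TRUE),
                                 c(C = -1, CDX = 0, MLX = 1))$category, 6L)

  # no significant pairs -> 0
  expect_equal(classify_category(mk_sig(FALSE, FALSE, FALSE),
                                 means_up4)$category, 0L)

  # CDX-only pattern -> category 2, direction from CDX vs C
  r2 <- classify_category(mk_sig(TRUE, FALSE, TRUE), c(C = 0, CDX = 2, MLX = 0.1))
  expect_equal(r2$category, 2L)
  expect_equal(r2$direction, "up")

  # MLX-only pattern -> category 3
  r3 <- classify_category(mk_sig(FALSE, TRUE, TRUE), c(C = 0, CDX = 0.1, MLX = -2))
  expect_equal(r3$category, 3L)
  expect_equal(r3$direction, "down")

  # shared CDX/MLX deviation, same direction -> 1; opposite -> 0
  r1 <- classify_category(mk_sig(TRUE, TRUE, FALSE), c(C = 0, CDX = 1, MLX = 1.1))
  expect_equal(r1$category, 1L)
  r0 <- classify_category(mk_sig(TRUE, TRUE, FALSE), c(C = 0, CDX = 1, MLX = -1))
  expect_equal(r0$category, 0L)
  expect_match(r0$reason, "opposite")

  # a single significant pair is unclassifiable
  rs <- classify_category(mk_sig(TRUE, FALSE, FALSE), means_up4)
  expect_equal(rs$category, 0L)
  expect_match(rs$reason, "single")

  # lenient mode promotes CDX-MLX + one other to an ordered category
  rl <- classify_category(mk_sig(TRUE, FALSE, TRUE), means_up4,
                          mode = "lenient")
  expect_equal(rl$category, 4L)
})

test_that("full DE analysis recovers planted categories on the 18-array design", {
  d <- generate_design()
  sim <- generate_expression(
    d, 800, c("1" = 0.05, "2" = 0.05, "3" = 0.05, "4" = 0.05),
    effect_size = 1.5, population_sd = 0.1, residual_sd = 0.3, seed = 15
  )
  de <- de_analysis(sim$expression, d)
  joined <- dplyr::left_join(tibble::as_tibble(de), sim$truth,
                             by = "transcript_id")
  planted <- joined[joined$planted_category %in% 1:4, ]
  recovery <- mean(planted$category == planted$planted_category)
  expect_gte(recovery, 0.85)

  # planted direction is recovered too when the category is right
  ok <- planted[planted$category == planted$planted_category, ]
  expect_gte(mean(ok$direction.x == ok$direction.y), 0.95)

  # nulls stay mostly unclassified
  nulls <- joined[joined$planted_category == 0, ]
  expect_lte(mean(nulls$category > 0), 0.02)
})

test_that("DE tibble carries the FDR gate and glance summary", {
  d <- generate_design()
  sim <- generate_expression(d, 100, c("4" = 0.1), seed = 16)
  de <- de_analysis(sim$expression, d)
  expect_true(all(de$overall_q >= de$overall_p))
  expect_true(all(de$category[de$overall_q > 0.05] == 0))
  gl <- generics::glance(de)
  expect_equal(gl$df1, 2)
  expect_equal(gl$df2, 6)
  cc <- category_counts(de)
  expect_equal(sum(cc$n), 100)
})
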