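toy_go_map <- function(term_members) {
  tibble::tibble(
    term_id = rep(names(term_members), lengths(term_members)),
    transcript_id = unlist(term_members, use.names = FALSE)
  )
}

test_that("hypergeometric GO test matches hand tail enumeration", {
  universe <- sprintf("g%02d", 1:20)
  # term of size 5, gene set of size 5, 3 in the term
  gm <- toy_go_map(list(T1 = universe[1:5], Tall = universe))
  gene_set <- c(universe[1:3], universe[18:19])
  res <- hypergeom_go(gene_set, universe, gm)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$observed, 3)
  expect_equal(r1$p_raw, 1126 / 15504, tolerance = 1e-12)
  # term covering the whole universe: observed = draws, p = 1
  expect_equal(res$p_raw[res$term_id == "Tall"], 1)

  # observed 0 with a nonempty term -> p = 1
  gm0 <- toy_go_map(list(T2 = universe[6:10]))
  res0 <- hypergeom_go(universe[1:3], universe, gm0)
  expect_equal(res0$p_raw, 1)

  expect_error(hypergeom_go(c("nope"), universe, gm), "not in universe")
})

test_that("hypergeometric p equals exact enumeration on small universes", {
  withr::local_seed(21)
  for (i in 1:50) {
    n_uni <- sample(8:25, 1)
    universe <- sprintf("u%02d", seq_len(n_uni))
    term <- sample(universe, sample(2:(n_uni - 1), 1))
    gene_set <- sample(universe, sample(2:(n_uni - 1), 1))
    res <- hypergeom_go(gene_set, universe, toy_go_map(list(T = term)))
    expect_equal(res$p_raw,
                 oracle_hyper_tail(res$observed, length(term), n_uni,
                                   length(gene_set)),
                 tolerance = 1e-12)
  }
})

test_that("chromosomal chi-square matches hand computation and chisq.test", {
  ann <- tibble::tibble(
    transcript_id = sprintf("g%02d", 1:40),
    chromosome = rep(c("X", "2", "3", "4"), each = 10)
  )
  universe <- ann$transcript_id

  # set drawn exactly proportional to the universe -> chi2 = 0
  prop_set <- sprintf("g%02d", c(1:3, 11:13, 21:23, 31:33))
  expect_equal(chrom_chisq(prop_set, ann, universe)$statistic, 0)

  # observed (6,2,2,2) vs uniform expected (3,3,3,3) -> chi2 = 4, df = 3
  set <- sprintf("g%02d", c(11:16, 21:22, 31:32, 1:2))  # 6 on "2"
  res <- chrom_chisq(set, ann, universe)
  expect_equal(res$statistic, 4.0, tolerance = 1e-12)
  expect_equal(res$df, 3)
  # independent check with chisq.test on the package's own table
  ct2 <- suppressWarnings(stats::chisq.test(res$observed,
                                            p = res$expected / sum(res$expected)))
  expect_equal(res$statistic, unname(ct2$statistic), tolerance = 1e-12)
  expect_equal(res$p, ct2$p.value, tolerance = 1e-12)

  # excluding chromosome 4 drops to df = 2 and renormalises expectations
  res4 <- chrom_chisq(set, ann, universe, exclude_chromosomes = "4")
  expect_equal(res4$df, 2)
  expect_equal(sum(res4$expected), sum(res4$observed), tolerance = 1e-12)
})

test_that("tissue Fisher test matches the single-table hypergeometric term", {
  universe <- sprintf("g%02d", 1:10)
  sets <- list(gut = universe[1:2])
  res <- tissue_fisher(universe[1:2], sets, universe)
  expect_equal(res$p_raw, 1 / 45, tolerance = 1e-12)  # C(2,2)/C(10,2)

  # empty gene set -> p = 1
  res0 <- tissue_fisher(character(), sets, universe)
  expect_equal(res0$p_raw, 1)

  # Bonferroni: 17 tissues multiply raw p, capped at 1
  sets17 <- stats::setNames(rep(list(universe[1:2]), 17),
                            paste0("t", 1:17))
  res17 <- tissue_fisher(universe[1:2], sets17, universe,
                         strict_panel = TRUE)
  expect_equal(res17$p_adjusted, pmin(1, 17 * res17$p_raw))
  expect_true(all(res17$p_adjusted <= 1))
  expect_error(tissue_fisher(universe[1], sets, universe,
                             strict_panel = TRUE), "17")

  # one-tailed Fisher p equals the hypergeometric upper tail
  withr::local_seed(22)
  for (i in 1:25) {
    n_uni <- sample(10:25, 1)
    uni <- sprintf("x%02d", seq_len(n_uni))
    spec <- sample(uni, sample(2:(n_uni - 2), 1))
    gs <- sample(uni, sample(2:(n_uni - 2), 1))
    res <- tissue_fisher(gs, list(t = spec), uni)
    expect_equal(res$p_raw,
                 oracle_hyper_tail(res$observed, length(spec), n_uni,
                                   length(gs)),
                 tolerance = 1e-10)
  }
})

test_that("MR-GSE statistic and exact permutation match full enumeration", {
  ranking <- stats::setNames(5:1, paste0("g", 1:5))  # g1 has rank 1

  # ranks {1, 2}: mean 1.5; enumeration over C(5,2) subsets -> p = 0.2
  res <- mr_gse(c("g1", "g2"), ranking, method = "exact")
  expect_equal(res$mean_rank, 1.5)
  expect_equal(res$p, 0.2, tolerance = 1e-12)
  expect_equal(res$p, oracle_mrgse_exact(c(1, 2), 5), tolerance = 1e-12)

  # symmetric set about (N+1)/2 -> z = 0, p = 1
  res_sym <- mr_gse(c("g1", "g5"), ranking, method = "normal")
  expect_equal(res_sym$z, 0)
  expect_equal(res_sym$p, 1)

  # null moments: mean (N+1)/2, variance (N-n)(N+1)/(12n)
  expect_equal(res$null_mean, 3)
  expect_equal(res$null_sd, sqrt((5 - 2) * 6 / (12 * 2)))

  expect_error(mr_gse(paste0("g", 1:5), ranking), "strict subset")
  expect_error(mr_gse("absent", ranking), "missing from ranking")
})

test_that("MR-GSE exact mode equals subset enumeration on random instances", {
  withr::local_seed(23)
  for (i in 1:20) {
    n_total <- sample(6:12, 1)
    n <- sample(2:4, 1)
    ranking <- stats::setNames(sample(n_total), paste0("g", seq_len(n_total)))
    gs <- sample(names(ranking), n)
    res <- mr_gse(gs, ranking, method = "exact")
    ranks <- rank(-ranking)[gs]
    expect_equal(res$p, oracle_mrgse_exact(ranks, n_total), tolerance = 1e-10)
  }
})

test_that("MR-GSE normal approximation tracks the exact p for moderate sets", {
  withr::local_seed(24)
  for (i in 1:20) {
    n_total <- sample(200:400, 1)
    n <- sample(20:40, 1)
    ranking <- stats::setNames(rnorm(n_total), paste0("g", seq_len(n_total)))
    gs <- sample(names(ranking), n)
    p_norm <- mr_gse(gs, ranking, method = "normal")$p
    p_exact <- mr_gse(gs, ranking, method = "exact")$p
    expect_lt(abs(p_norm - p_exact), 0.01)
  }
})

test_that("MR-GSE p-values are uniform under random gene sets", {
  withr::local_seed(25)
  n_total <- 500
  ranking <- stats::setNames(rnorm(n_total), paste0("g", seq_len(n_total)))
  pvals <- vapply(1:400, function(i) {
    mr_gse(sample(names(ranking), 30), ranking, method = "normal")$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("MR-GSE detects planted score boosts through the annotation table", {
  boosted <- sprintf("tx%05d", 1:30)
  ann <- generate_annotations(500, boost_male_fitness = boosted,
                              score_boost = 3, seed = 26)
  ranking <- stats::setNames(ann$male_fitness_score, ann$transcript_id)
  res <- mr_gse(boosted, ranking)
  expect_lt(res$p, 1e-6)
  expect_lt(res$z, 0)  # boosted set sits at the top ranks (small mean rank)
})
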