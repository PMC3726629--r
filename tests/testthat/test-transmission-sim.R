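test_that("SA fitness functions match hand evaluation", {
  expect_equal(male_fitness(c(0, 0, 0), 0.1), 1.0)
  expect_equal(male_fitness(c(1, 1, 1), 0.1), 1.1^3)  # 1.331
  expect_equal(female_fitness(c(1, 0), c(0, 0), 0.2), 0.8^0.5)
  expect_equal(female_fitness(c(0, 0), c(0, 0), 0.5), 1.0)
  expect_error(male_fitness(c(0, 2), 0.1), "0/1")
})

test_that("DX cross forces father-son X transmission and kills XXX/YY zygotes", {
  withr::local_seed(1)
  father <- individual_male(c(1L, 0L, 1L, 1L), y_tag = 7L)
  mother <- individual_dx_female(y_tag = 3L)

  expect_identical(cross_dx(father, mother, 0), list())
  expect_error(cross_dx(mother, father, 5), "karyotype")

  kids <- cross_dx(father, mother, 2000)
  karyo <- vapply(kids, `[[`, character(1), "karyotype")
  expect_true(all(karyo %in% c("male", "dx_female")))  # no XXX, no YY
  sons <- kids[karyo == "male"]
  for (s in sons) {
    expect_identical(s$x[[1]], father$x[[1]])  # exact paternal X copy
    expect_identical(s$y_tag, mother$y_tag)    # maternal Y
  }
  daughters <- kids[karyo == "dx_female"]
  expect_true(all(vapply(daughters, `[[`, integer(1), "y_tag") == 7L))
})

test_that("DX cross viability is one half with sons and DX daughters at 1:1", {
  withr::local_seed(2)
  n <- 1e5
  kids <- cross_dx(individual_male(c(1L, 0L)), individual_dx_female(), n)
  viable <- length(kids) / n
  sigma <- sqrt(0.25 / n)
  expect_lt(abs(viable - 0.5), 3 * sigma)
  n_sons <- sum(vapply(kids, `[[`, character(1), "karyotype") == "male")
  expect_lt(abs(n_sons / length(kids) - 0.5),
            3 * sqrt(0.25 / length(kids)))
})

test_that("wildtype cross segregates X chromosomes correctly", {
  withr::local_seed(3)
  father <- individual_male(rep(1L, 4))
  mother <- individual_female(rep(0L, 4), c(1L, 1L, 0L, 0L))

  # recombination rate 0: every gamete is an unmodified parental haplotype
  kids <- cross_wildtype(father, mother, 200, recombination_rate = 0)
  for (k in kids) {
    maternal <- if (k$karyotype == "male") k$x[[1]] else k$x[[2]]
    expect_true(identical(maternal, mother$x[[1]]) ||
                  identical(maternal, mother$x[[2]]))
    if (k$karyotype == "female") expect_identical(k$x[[1]], father$x[[1]])
  }

  # sons draw only maternal X: all-1 father, all-0 mother -> sons all-0
  mother0 <- individual_female(rep(0L, 4), rep(0L, 4))
  kids2 <- cross_wildtype(father, mother0, 300, recombination_rate = 0.5)
  sons <- Filter(function(k) k$karyotype == "male", kids2)
  expect_gt(length(sons), 0)
  for (s in sons) expect_true(all(s$x[[1]] == 0L))

  expect_error(cross_wildtype(father, individual_dx_female(), 5), "karyotype")
})

test_that("free recombination at L = 2 yields all four gametes near equifrequency", {
  withr::local_seed(4)
  mother <- individual_female(c(0L, 0L), c(1L, 1L))
  father <- individual_male(c(0L, 0L))
  n <- 4000
  kids <- cross_wildtype(father, mother, n, recombination_rate = 0.5)
  gametes <- vapply(kids, function(k) {
    g <- if (k$karyotype == "male") k$x[[1]] else k$x[[2]]
    paste(g, collapse = "")
  }, character(1))
  counts <- table(factor(gametes, levels = c("00", "01", "10", "11")))
  for (cnt in counts) {
    sigma <- sqrt(length(kids) * 0.25 * 0.75)
    expect_lt(abs(cnt - length(kids) / 4), 3 * sigma)
  }
})

test_that("simulation bookkeeping: sizes, bounds, determinism, errors", {
  tr <- run_mlx_simulation(L = 8, s_male = 0.1, s_female = 0.1,
                           n_main = 60, n_rb = 8, migrants_per_gen = 4,
                           generations = 10, seed = 5)
  expect_equal(nrow(tr), 11)
  expect_true(all(tr$allele_freq >= 0 & tr$allele_freq <= 1))
  expect_true(all(tr$mean_male_fitness >= 1))
  tr2 <- run_mlx_simulation(L = 8, s_male = 0.1, s_female = 0.1,
                            n_main = 60, n_rb = 8, migrants_per_gen = 4,
                            generations = 10, seed = 5)
  expect_identical(tr, tr2)

  expect_error(run_mlx_simulation(n_rb = 0, migrants_per_gen = 4),
               "recombination box")

  ctrl <- run_mlx_simulation(L = 8, n_main = 60, generations = 5,
                             mode = "Control", seed = 6)
  expect_equal(ctrl$mode[1], "Control")
  expect_false(any(is.na(ctrl$mean_female_fitness)))
})

test_that("MLX without RB exchange only resamples existing X haplotypes", {
  tr <- run_mlx_simulation(L = 10, s_male = 0.2, s_female = 0,
                           n_main = 80, n_rb = 0, migrants_per_gen = 0,
                           generations = 8, record_haplotypes = TRUE,
                           seed = 7)
  haps <- attr(tr, "haplotypes")
  for (g in 2:length(haps)) {
    prev <- apply(haps[[g - 1]], 1, paste, collapse = "")
    cur <- apply(haps[[g]], 1, paste, collapse = "")
    expect_true(all(cur %in% prev))  # no recombination possible
    expect_equal(nrow(haps[[g]]), 40)  # constant population size
  }
})

test_that("neutral allele frequencies behave as a martingale", {
  finals <- vapply(1:120, function(s) {
    tr <- run_mlx_simulation(L = 10, s_male = 0, s_female = 0,
                             init_freq = 0.5, n_main = 100, n_rb = 10,
                             migrants_per_gen = 5, generations = 10,
                             seed = 1000 + s)
    tr$allele_freq[nrow(tr)]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * se)
})

test_that("selection drives male-benefit alleles higher under MLX than Control", {
  diffs <- vapply(1:25, function(s) {
    mlx <- run_mlx_simulation(L = 15, s_male = 0.15, s_female = 0.1,
                              n_main = 120, n_rb = 12, migrants_per_gen = 6,
                              generations = 20, mode = "MLX",
                              seed = 2000 + s)
    ctl <- run_mlx_simulation(L = 15, s_male = 0.15, s_female = 0.1,
                              n_main = 120, generations = 20,
                              mode = "Control", seed = 2000 + s)
    mlx$allele_freq[nrow(mlx)] - ctl$allele_freq[nrow(ctl)]
  }, numeric(1))
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)
})
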