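# Independent oracles used across test files.

# Brute-force nested ANOVA through R's linear-model machinery:
# fit y ~ treatment/population and form F = MS(Treatment) / MS(Pop within
# Treatment). Entirely independent of the package's sums-of-squares path.
oracle_nested_anova <- function(values, design) {
  df <- data.frame(
    y = as.numeric(values),
    trt = factor(design$treatment),
    pop = factor(design$population)
  )
  an <- stats::anova(stats::lm(y ~ trt / pop, data = df))
  ms_t <- an["trt", "Mean Sq"]
  ms_p <- an["trt:pop", "Mean Sq"]
  f <- ms_t / ms_p
  df1 <- an["trt", "Df"]
  df2 <- an["trt:pop", "Df"]
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Exact upper-tail hypergeometric by direct enumeration of the tail.
oracle_hyper_tail <- function(observed, term_size, universe_size, draws) {
  ks <- observed:min(term_size, draws)
  sum(choose(term_size, ks) * choose(universe_size - term_size, draws - ks)) /
    choose(universe_size, draws)
}

# Exact two-tailed MR-GSE p by full enumeration of all size-n subsets.
oracle_mrgse_exact <- function(set_ranks, n_total) {
  n <- length(set_ranks)
  obs_dev <- abs(mean(set_ranks) - (n_total + 1) / 2)
  subsets <- utils::combn(n_total, n)
  devs <- abs(colMeans(subsets) - (n_total + 1) / 2)
  mean(devs >= obs_dev - 1e-12)
}
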