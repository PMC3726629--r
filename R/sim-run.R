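#' Forward-time simulation of MLX or Control evolution
#'
#' Individual-based, discrete non-overlapping generations. In `MLX`
#' mode the main population consists of wildtype males and DX females:
#' every son inherits his father's X unchanged (fathers sampled in
#' proportion to male fitness), so selection on the X acts through males
#' only. A recombination-box (RB) satellite population of wildtype flies
#' exchanges `migrants_per_gen` males with the main population each
#' generation, letting X haplotypes recombine. In `Control` mode a
#' single wildtype population evolves under selection on both sexes
#' with standard X transmission.
#'
#' The mating ecology is abstracted into fitness-proportional paternity
#' (and maternity, where females are wildtype); fitness follows
#' [male_fitness()] / [female_fitness()]. X-Y recombination in DX
#' females is not modelled.
#'
#' @param L Number of sexually antagonistic loci on the X.
#' @param s_male,s_female Selection coefficients per male-benefit
#'   allele.
#' @param init_freq Initial male-benefit allele frequency at every
#'   locus.
#' @param n_main Total main-population size (half males; 640 in the
#'   canonical protocol).
#' @param n_rb RB individuals per sex (32 in the canonical protocol).
#' @param migrants_per_gen Males exchanged with the RB each generation
#'   (32 in the canonical protocol).
#' @param generations Number of generations to run.
#' @param mode `"MLX"` or `"Control"`.
#' @param recombination_rate Per-adjacent-locus crossover probability in
#'   wildtype females.
#' @param rb_selection Apply SA selection inside the RB (default TRUE).
#' @param record_haplotypes Also return the main-population male X
#'   matrix for every generation.
#' @param seed Integer seed.
#' @return Tibble of class `mlx_trajectory`: `generation` (0 = initial
#'   state), `mode`, `allele_freq` (mean male-benefit frequency on main-
#'   population X copies), `mean_male_fitness`, `mean_female_fitness`
#'   (RB females in MLX mode, NA if no RB). With
#'   `record_haplotypes = TRUE`, the per-generation X matrices are
#'   attached as attribute `"haplotypes"`.
#' @examples
#' run_mlx_simulation(L = 10, s_male = 0.1, s_female = 0.05,
#'                    n_main = 100, n_rb = 10, migrants_per_gen = 5,
#'                    generations = 5, seed = 1)
#' @export
run_mlx_simulation <- function(L = 20, s_male = 0.05, s_female = 0.05,
                               init_freq = 0.5, n_main = 640, n_rb = 32,
                               migrants_per_gen = 32, generations = 20,
                               mode = c("MLX", "Control"),
                               recombination_rate = 0.5,
                               rb_selection = TRUE,
                               record_haplotypes = FALSE,
                               seed = NULL) {
  mode <- match.arg(mode)
  assert_count(L, "L")
  assert_count(n_main, "n_main", min = 2L)
  assert_count(generations, "generations", min = 0L)
  assert_count(n_rb, "n_rb", min = 0L)
  assert_count(migrants_per_gen, "migrants_per_gen", min = 0L)
  assert_prob(init_freq, "init_freq")
  assert_prob(recombination_rate, "recombination_rate")
  stopifnot(s_male >= 0, s_male < 1, s_female >= 0, s_female < 1)
  if (mode == "MLX") {
    if (n_rb == 0 && migrants_per_gen > 0) {
      abort("migrants_per_gen > 0 requires a recombination box (n_rb > 0)")
    }
    if (migrants_per_gen > n_rb || migrants_per_gen > n_main %/% 2) {
      abort("migrants_per_gen cannot exceed the male pool on either side")
    }
  }

  with_seed_or_not(seed, {
    if (mode == "MLX") sim_mlx(L, s_male, s_female, init_freq, n_main, n_rb,
                               migrants_per_gen, generations,
                               recombination_rate, rb_selection,
                               record_haplotypes)
    else sim_control(L, s_male, s_female, init_freq, n_main, generations,
                     recombination_rate, record_haplotypes)
  })
}

draw_haplotypes <- function(n, L, freq) {
  matrix(as.integer(runif(n * L) < freq), n, L)
}

male_w <- function(X, s) (1 + s)^rowSums(X)
female_w <- function(X1, X2, s) (1 - s)^((rowSums(X1) + rowSums(X2)) / 2)

sample_idx <- function(n_draw, weights) {
  sample.int(length(weights), n_draw, replace = TRUE, prob = weights)
}

sim_mlx <- function(L, s_m, s_f, p0, n_main, n_rb, n_mig, gens, r_rate,
                    rb_sel, record) {
  n_males <- n_main %/% 2
  Xm <- draw_haplotypes(n_males, L, p0)             # main-pop male X
  rb_m <- draw_haplotypes(n_rb, L, p0)              # RB males
  rb_f1 <- draw_haplotypes(n_rb, L, p0)             # RB females, 2 copies
  rb_f2 <- draw_haplotypes(n_rb, L, p0)

  snap <- function(gen) {
    tibble::tibble(
      generation = gen, mode = "MLX",
      allele_freq = mean(Xm),
      mean_male_fitness = mean(male_w(Xm, s_m)),
      mean_female_fitness = if (n_rb > 0) mean(female_w(rb_f1, rb_f2, s_f))
                            else NA_real_
    )
  }
  traj <- vector("list", gens + 1)
  haps <- if (record) vector("list", gens + 1) else NULL
  traj[[1]] <- snap(0L)
  if (record) haps[[1]] <- Xm

  for (g in seq_len(gens)) {
    # migration: n_mig random main males join the RB male pool and
    # n_mig random RB males join the main male pool
    if (n_mig > 0) {
      to_rb <- sample.int(n_males, n_mig)
      to_main <- sample.int(n_rb, n_mig)
      main_pool <- rbind(Xm, rb_m[to_main, , drop = FALSE])
      rb_pool <- rbind(rb_m, Xm[to_rb, , drop = FALSE])
    } else {
      main_pool <- Xm
      rb_pool <- rb_m
    }

    # main population: DX cross; sons copy their father's X
    fathers <- sample_idx(n_males, male_w(main_pool, s_m))
    Xm_next <- main_pool[fathers, , drop = FALSE]

    # RB: wildtype breeding, optional selection on both sexes
    if (n_rb > 0) {
      w_m <- if (rb_sel) male_w(rb_pool, s_m) else rep(1, nrow(rb_pool))
      w_f <- if (rb_sel) female_w(rb_f1, rb_f2, s_f) else rep(1, n_rb)
      f_son <- sample_idx(n_rb, w_m)
      m_son <- sample_idx(n_rb, w_f)
      rb_m_next <- recombine_rows(rb_f1[m_son, , drop = FALSE],
                                  rb_f2[m_son, , drop = FALSE], r_rate)
      f_dau <- sample_idx(n_rb, w_m)
      m_dau <- sample_idx(n_rb, w_f)
      rb_f1_next <- rb_pool[f_dau, , drop = FALSE]
      rb_f2_next <- recombine_rows(rb_f1[m_dau, , drop = FALSE],
                                   rb_f2[m_dau, , drop = FALSE], r_rate)
      rb_m <- rb_m_next; rb_f1 <- rb_f1_next; rb_f2 <- rb_f2_next
    }
    Xm <- Xm_next
    traj[[g + 1]] <- snap(g)
    if (record) haps[[g + 1]] <- Xm
  }
  finish_trajectory(traj, haps)
}

sim_control <- function(L, s_m, s_f, p0, n_main, gens, r_rate, record) {
  n_m <- n_main %/% 2
  n_f <- n_main - n_m
  Xm <- draw_haplotypes(n_m, L, p0)
  Xf1 <- draw_haplotypes(n_f, L, p0)
  Xf2 <- draw_haplotypes(n_f, L, p0)

  snap <- function(gen) {
    tibble::tibble(
      generation = gen, mode = "Control",
      allele_freq = (sum(Xm) + sum(Xf1) + sum(Xf2)) / ((n_m + 2 * n_f) * L),
      mean_male_fitness = mean(male_w(Xm, s_m)),
      mean_female_fitness = mean(female_w(Xf1, Xf2, s_f))
    )
  }
  traj <- vector("list", gens + 1)
  haps <- if (record) vector("list", gens + 1) else NULL
  traj[[1]] <- snap(0L)
  if (record) haps[[1]] <- Xm

  for (g in seq_len(gens)) {
    w_m <- male_w(Xm, s_m)
    w_f <- female_w(Xf1, Xf2, s_f)
    # sons: maternal recombinant X
    m_son <- sample_idx(n_m, w_f)
    Xm_next <- recombine_rows(Xf1[m_son, , drop = FALSE],
                              Xf2[m_son, , drop = FALSE], r_rate)
    # daughters: paternal X + maternal recombinant
    f_dau <- sample_idx(n_f, w_m)
    m_dau <- sample_idx(n_f, w_f)
    Xf1_next <- Xm[f_dau, , drop = FALSE]
    Xf2_next <- recombine_rows(Xf1[m_dau, , drop = FALSE],
                               Xf2[m_dau, , drop = FALSE], r_rate)
    Xm <- Xm_next; Xf1 <- Xf1_next; Xf2 <- Xf2_next
    traj[[g + 1]] <- snap(g)
    if (record) haps[[g + 1]] <- Xm
  }
  finish_trajectory(traj, haps)
}

finish_trajectory <- function(traj, haps) {
  out <- dplyr::bind_rows(traj)
  class(out) <- c("mlx_trajectory", class(out))
  if (!is.null(haps)) attr(out, "haplotypes") <- haps
  out
}
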