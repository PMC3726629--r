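#' Construct simulated individuals
#'
#' Individuals for the DX-cross simulator. A wildtype male carries one X
#' haplotype and a Y; a wildtype female two X haplotypes; a compound-X
#' (DX) female carries two X chromosomes fused at the centromere —
#' transmitted as a unit and never expressed in males — plus a Y.
#' Haplotypes are 0/1 vectors over L sexually antagonistic loci
#' (1 = male-benefit / female-detriment allele).
#'
#' @param x,x1,x2 Integer 0/1 haplotype vectors.
#' @param y_tag Y-chromosome lineage identifier.
#' @return A list of class `mlx_individual` with elements `karyotype`
#'   (`"male"`, `"female"`, `"dx_female"`), `x` (list of haplotypes) and
#'   `y_tag`.
#' @export
individual_male <- function(x, y_tag = 1L) {
  new_individual("male", list(check_haplotype(x)), y_tag)
}

#' @rdname individual_male
#' @export
individual_female <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  new_individual("female", list(check_haplotype(x1), check_haplotype(x2)), NA)
}

#' @rdname individual_male
#' @export
individual_dx_female <- function(y_tag = 1L) {
  new_individual("dx_female", list(), y_tag)
}

new_individual <- function(karyotype, x, y_tag) {
  structure(list(karyotype = karyotype, x = x, y_tag = y_tag),
            class = "mlx_individual")
}

check_haplotype <- function(x) {
  if (!is.numeric(x) || any(!(x %in% c(0, 1)))) {
    abort("haplotypes must be 0/1 vectors")
  }
  as.integer(x)
}

#' Male and female fitness under multiplicative SA selection
#'
#' Male-benefit alleles multiply male fitness by (1 + s_male) per copy
#' on the hemizygous X, and female fitness by (1 - s_female) per allele
#' copy over the diploid count divided by two (semidominant).
#'
#' @param h,h1,h2 0/1 haplotype vectors.
#' @param s_male,s_female Selection coefficients in [0, 1).
#' @return Positive fitness value.
#' @examples
#' male_fitness(c(1, 1, 1), 0.1)            # 1.1^3
#' female_fitness(c(1, 0), c(0, 0), 0.2)    # 0.8^0.5
#' @export
male_fitness <- function(h, s_male) {
  stopifnot(s_male >= 0, s_male < 1)
  (1 + s_male)^sum(check_haplotype(h))
}

#' @rdname male_fitness
#' @export
female_fitness <- function(h1, h2, s_female) {
  stopifnot(s_female >= 0, s_female < 1)
  n <- sum(check_haplotype(h1)) + sum(check_haplotype(h2))
  (1 - s_female)^(n / 2)
}

#' Cross a wildtype male to a DX female
#'
#' The cross behind male-limited X transmission: the father's X-bearing
#' sperm can only make a viable zygote with the mother's Y-bearing egg
#' (a wildtype son with the father's X and the mother's Y), and his
#' Y-bearing sperm only with her compound-X egg (a new DX daughter with
#' the father's Y). Triple-X and YY zygotes die, so half of all zygotes
#' survive, sons and DX daughters in equal expected numbers — and every
#' surviving son's X is an exact copy of his father's.
#'
#' @param father `mlx_individual` with karyotype `"male"`.
#' @param mother `mlx_individual` with karyotype `"dx_female"`.
#' @param n_offspring Number of zygotes to draw.
#' @return List of surviving offspring (`mlx_individual`).
#' @export
cross_dx <- function(father, mother, n_offspring) {
  check_karyotype(father, "male")
  check_karyotype(mother, "dx_female")
  assert_count(n_offspring, "n_offspring", min = 0L)
  if (n_offspring == 0) return(list())
  # sperm X/Y and egg Y/compound-X combine independently; only
  # (X sperm, Y egg) and (Y sperm, DX egg) survive
  sperm_x <- runif(n_offspring) < 0.5
  egg_y <- runif(n_offspring) < 0.5
  out <- list()
  for (i in seq_len(n_offspring)) {
    if (sperm_x[i] && egg_y[i]) {
      out[[length(out) + 1L]] <- individual_male(father$x[[1]], mother$y_tag)
    } else if (!sperm_x[i] && !egg_y[i]) {
      out[[length(out) + 1L]] <- individual_dx_female(father$y_tag)
    } # XX-compound + X and Y + Y are inviable
  }
  out
}

#' Cross two wildtype individuals
#'
#' Standard XY segregation with recombination between the mother's two X
#' haplotypes: each maternal gamete is a recombinant of her two Xs
#' (crossover between adjacent loci with the given probability).
#' Daughters receive the father's X plus a maternal recombinant; sons a
#' maternal recombinant plus the father's Y.
#'
#' @param father `mlx_individual`, karyotype `"male"`.
#' @param mother `mlx_individual`, karyotype `"female"`.
#' @param n_offspring Number of offspring.
#' @param recombination_rate Per-adjacent-locus crossover probability.
#' @return List of offspring (`mlx_individual`).
#' @export
cross_wildtype <- function(father, mother, n_offspring,
                           recombination_rate = 0.5) {
  check_karyotype(father, "male")
  check_karyotype(mother, "female")
  assert_count(n_offspring, "n_offspring", min = 0L)
  assert_prob(recombination_rate, "recombination_rate")
  out <- vector("list", n_offspring)
  for (i in seq_len(n_offspring)) {
    gamete <- recombine_haplotypes(mother$x[[1]], mother$x[[2]],
                                   recombination_rate)
    if (runif(1) < 0.5) {
      out[[i]] <- individual_male(gamete, father$y_tag)
    } else {
      out[[i]] <- individual_female(father$x[[1]], gamete)
    }
  }
  out
}

check_karyotype <- function(ind, expected) {
  if (!inherits(ind, "mlx_individual") || ind$karyotype != expected) {
    abort(sprintf("expected an individual with karyotype '%s'", expected))
  }
  invisible(ind)
}

# One recombinant gamete from two haplotypes.
recombine_haplotypes <- function(h1, h2, rate) {
  L <- length(h1)
  strand <- cumsum(c(sample(0:1, 1), runif(L - 1) < rate)) %% 2
  ifelse(strand == 0, h1, h2)
}

# Vectorised: one recombinant gamete per row of H1/H2.
recombine_rows <- function(H1, H2, rate) {
  n <- nrow(H1); L <- ncol(H1)
  if (n == 0) return(H1)
  breaks <- matrix(runif(n * (L - 1)) < rate, n, L - 1)
  strand <- t(apply(cbind(sample(0:1, n, replace = TRUE), breaks), 1,
                    cumsum)) %% 2
  strand <- matrix(strand, n, L)
  H1 * (strand == 0) + H2 * (strand == 1)
}
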