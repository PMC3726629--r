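#' Default tissue panel
#'
#' Seventeen adult fly tissues, mirroring the size of the tissue atlas
#' panel used for two-fold tissue-specificity calls.
#' @export
fly_tissues <- function() {
  c("brain", "head", "eye", "thoracic_ganglion", "salivary_gland",
    "crop", "midgut", "hindgut", "malpighian_tubule", "fat_body",
    "ovary", "testis", "accessory_gland", "ejaculatory_duct",
    "heart", "carcass", "larval_fat_body")
}

#' Default fly-like chromosome weights
#' @export
fly_chromosome_weights <- function() {
  c(X = 0.16, `2` = 0.40, `3` = 0.42, `4` = 0.02)
}

#' Generate a synthetic transcript annotation table
#'
#' Stand-in for the chromosome map, GO annotation, tissue-specificity
#' calls (two-fold-over-whole-fly rule on a 17-tissue atlas) and
#' fitness-association rankings that the enrichment batteries consume.
#' Everything is drawn with known structure so recovery tests have ground
#' truth.
#'
#' Fitness scores are standard-normal association statistics used only
#' for ranking. To plant an MR-GSE signal, pass transcript ids in
#' `boost_male_fitness` / `boost_antagonism`: those transcripts get
#' `score_boost` added to the corresponding score. To plant a feminized
#' sex-bias pattern, pass `couple_sign` (a named vector of -1/0/+1 per
#' transcript, e.g. `sign(delta_CDX)` from the expression truth table):
#' with probability `coupling` a transcript's `sex_bias_sign` is copied
#' from it instead of drawn independently.
#'
#' @param n_transcripts Number of transcripts (ids must match the
#'   expression simulation: `tx00001`, ...).
#' @param chromosome_weights Named non-negative weights over chromosomes.
#' @param n_go_terms Number of GO-like terms.
#' @param go_term_size_range Integer pair: min/max transcripts per term.
#' @param tissues Character vector of tissue names (17 in the canonical protocol).
#' @param tissue_set_fraction Expected fraction of transcripts specific
#'   to each tissue.
#' @param sex_bias_prob Probability that a non-zero sex bias is +1
#'   (female-biased).
#' @param zero_bias_fraction Fraction of transcripts with no sex bias.
#' @param boost_male_fitness,boost_female_fitness,boost_antagonism
#'   Transcript ids whose scores are shifted by `score_boost`.
#' @param score_boost Shift added to boosted scores.
#' @param couple_sign Optional named -1/0/+1 vector for feminized
#'   coupling of `sex_bias_sign`.
#' @param coupling Probability of copying `couple_sign`.
#' @param strict_panel If `TRUE`, require exactly 17 tissues.
#' @param seed Integer seed.
#' @return Tibble with one row per transcript: `transcript_id`,
#'   `chromosome`, `go_terms` (list), `tissue_specific_in` (list),
#'   `sex_bias_sign`, `male_fitness_score`, `female_fitness_score`,
#'   `antagonism_score`.
#' @export
generate_annotations <- function(n_transcripts,
                                 chromosome_weights = fly_chromosome_weights(),
                                 n_go_terms = 50,
                                 go_term_size_range = c(5, 50),
                                 tissues = fly_tissues(),
                                 tissue_set_fraction = 0.03,
                                 sex_bias_prob = 0.5,
                                 zero_bias_fraction = 0,
                                 boost_male_fitness = character(),
                                 boost_female_fitness = character(),
                                 boost_antagonism = character(),
                                 score_boost = 2,
                                 couple_sign = NULL,
                                 coupling = 0,
                                 strict_panel = TRUE,
                                 seed = NULL) {
  assert_count(n_transcripts, "n_transcripts")
  if (any(chromosome_weights < 0) || sum(chromosome_weights) <= 0) {
    abort("chromosome_weights must be non-negative and sum to > 0")
  }
  if (strict_panel && length(tissues) != 17) {
    abort("canonical-protocol tissue panel must have exactly 17 tissues")
  }
  assert_prob(tissue_set_fraction, "tissue_set_fraction")
  assert_prob(sex_bias_prob, "sex_bias_prob")
  assert_prob(zero_bias_fraction, "zero_bias_fraction")
  assert_prob(coupling, "coupling")

  transcript_id <- sprintf("tx%05d", seq_len(n_transcripts))
  with_seed_or_not(seed, {
    chromosome <- sample(names(chromosome_weights), n_transcripts,
                         replace = TRUE,
                         prob = chromosome_weights / sum(chromosome_weights))

    term_ids <- sprintf("GO:%07d", seq_len(n_go_terms))
    go_by_tx <- vector("list", n_transcripts)
    if (n_go_terms > 0) {
      sizes <- sample(go_term_size_range[1]:go_term_size_range[2],
                      n_go_terms, replace = TRUE)
      sizes <- pmin(sizes, n_transcripts)
      for (t in seq_len(n_go_terms)) {
        members <- sample.int(n_transcripts, sizes[t])
        for (i in members) go_by_tx[[i]] <- c(go_by_tx[[i]], term_ids[t])
      }
    }
    go_by_tx <- lapply(go_by_tx, function(x) if (is.null(x)) character() else x)

    tissue_by_tx <- replicate(n_transcripts, character(), simplify = FALSE)
    for (tis in tissues) {
      members <- which(runif(n_transcripts) < tissue_set_fraction)
      for (i in members) tissue_by_tx[[i]] <- c(tissue_by_tx[[i]], tis)
    }

    sex_bias_sign <- ifelse(runif(n_transcripts) < sex_bias_prob, 1L, -1L)
    sex_bias_sign[runif(n_transcripts) < zero_bias_fraction] <- 0L
    if (!is.null(couple_sign) && coupling > 0) {
      cs <- couple_sign[transcript_id]
      take <- !is.na(cs) & cs != 0 & runif(n_transcripts) < coupling
      sex_bias_sign[take] <- as.integer(cs[take])
    }

    score <- function(boost_ids) {
      s <- rnorm(n_transcripts)
      s[transcript_id %in% boost_ids] <-
        s[transcript_id %in% boost_ids] + score_boost
      s
    }

    tibble::tibble(
      transcript_id = transcript_id,
      chromosome = chromosome,
      go_terms = go_by_tx,
      tissue_specific_in = tissue_by_tx,
      sex_bias_sign = sex_bias_sign,
      male_fitness_score = score(boost_male_fitness),
      female_fitness_score = score(boost_female_fitness),
      antagonism_score = score(boost_antagonism)
    )
  })
}
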