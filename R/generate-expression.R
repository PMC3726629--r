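#' Treatment offsets for a planted transcript category
#'
#' Maps each of the six treatment-pattern categories onto log2 offsets
#' (`delta_C`, `delta_CDX`, `delta_MLX`) relative to the transcript
#' baseline, with Control always the reference (offset 0). Categories:
#'
#' 1. CDX and MLX shifted together relative to C (maternal effect of the
#'    DX females).
#' 2. CDX alone shifted (imprinting signature).
#' 3. MLX alone shifted (response to MLX evolution).
#' 4. Strict order CDX - C - MLX (fitness-related): offsets
#'    (-e, 0, +e) for the "up" variant.
#' 5. Strict order CDX - MLX - C: offsets (-2e, 0, -e).
#' 6. Strict order C - CDX - MLX: offsets (+e, 0, +2e).
#'
#' `direction = "down"` mirrors every offset. Category 0 is the null
#' (all offsets zero).
#'
#' @param category Integer 0-6.
#' @param effect_size Offset magnitude e, log2 units.
#' @param direction `"up"` or `"down"`.
#' @return Named numeric vector `c(C = , CDX = , MLX = )`.
#' @export
category_offsets <- function(category, effect_size, direction = "up") {
  stopifnot(category %in% 0:6, effect_size >= 0)
  direction <- match.arg(direction, c("up", "down"))
  e <- effect_size
  off <- switch(as.character(category),
    "0" = c(0, 0, 0),
    "1" = c(0, e, e),
    "2" = c(0, e, 0),
    "3" = c(0, 0, e),
    "4" = c(0, -e, e),
    "5" = c(0, -2 * e, -e),
    "6" = c(0, e, 2 * e)
  )
  if (direction == "down") off <- -off
  stats::setNames(off, TREATMENTS)
}

#' Generate a synthetic expression matrix with planted category effects
#'
#' Simulates normalized log2 expression for `n_transcripts` transcripts
#' over the samples of `design`, under exactly the variance structure the
#' nested ANOVA assumes: per-transcript baseline, fixed treatment offsets
#' determined by the planted category, a random population effect drawn
#' once per (transcript, population) and shared by that population's
#' replicate arrays, and independent residual noise per array.
#'
#' `category_fractions` assigns transcripts to the six treatment-pattern
#' categories (see [category_offsets()]); the remainder are null
#' (category 0). Planted categories split evenly between "up" and "down"
#' variants.
#'
#' @param design Sample design tibble from [generate_design()].
#' @param n_transcripts Number of transcripts.
#' @param category_fractions Named numeric vector, names in `"1"`-`"6"`,
#'   fractions summing to at most 1.
#' @param effect_size Planted offset magnitude, log2 units.
#' @param population_sd SD of the random population effect.
#' @param residual_sd SD of the array-level residual.
#' @param baseline_mean,baseline_sd Distribution of per-transcript
#'   baseline log2 intensity.
#' @param seed Integer seed; same arguments + seed give identical output.
#' @return A list with `expression` (tibble: `transcript_id` plus one
#'   column per `sample_id`), `truth` (tibble: `transcript_id`,
#'   `planted_category`, `direction`, `delta_C`, `delta_CDX`,
#'   `delta_MLX`), and `design`.
#' @examples
#' d <- generate_design()
#' sim <- generate_expression(d, 100, c("4" = 0.1), seed = 1)
#' table(sim$truth$planted_category)
#' @export
generate_expression <- function(design, n_transcripts,
                                category_fractions = c("3" = 0.02, "4" = 0.02),
                                effect_size = 1.5,
                                population_sd = 0.1,
                                residual_sd = 0.3,
                                baseline_mean = 7,
                                baseline_sd = 2,
                                seed = NULL) {
  validate_design(design)
  assert_count(n_transcripts, "n_transcripts")
  stopifnot(population_sd >= 0, residual_sd >= 0, effect_size >= 0)
  if (length(category_fractions) > 0) {
    if (is.null(names(category_fractions)) ||
        !all(names(category_fractions) %in% as.character(1:6))) {
      abort("category_fractions must be named with categories \"1\"..\"6\"")
    }
    if (any(category_fractions < 0) || sum(category_fractions) > 1 + 1e-12) {
      abort("category_fractions must be non-negative and sum to at most 1")
    }
  }

  n_samples <- nrow(design)
  transcript_id <- sprintf("tx%05d", seq_len(n_transcripts))

  # Deterministic category assignment by count (rounded down), then RNG
  # for the stochastic layers.
  counts <- floor(category_fractions * n_transcripts)
  cats <- integer(n_transcripts)
  pos <- 1L
  for (k in names(counts)) {
    n_k <- counts[[k]]
    if (n_k > 0) {
      cats[pos:(pos + n_k - 1L)] <- as.integer(k)
      pos <- pos + n_k
    }
  }

  with_seed_or_not(seed, {
    direction <- ifelse(cats == 0, "up",
                        sample(c("up", "down"), n_transcripts, replace = TRUE))
    offsets <- t(vapply(seq_len(n_transcripts), function(i) {
      category_offsets(cats[i], effect_size, direction[i])
    }, numeric(3)))
    colnames(offsets) <- TREATMENTS

    baseline <- rnorm(n_transcripts, baseline_mean, baseline_sd)

    # Population effects: one draw per (transcript, treatment, population)
    # cell, shared across replicates within that cell.
    cell_key <- paste(design$treatment, design$population)
    cells <- unique(cell_key)
    pop_eff <- matrix(rnorm(n_transcripts * length(cells), 0, population_sd),
                      nrow = n_transcripts,
                      dimnames = list(NULL, cells))

    trt_idx <- as.character(design$treatment)
    values <- matrix(0, n_transcripts, n_samples,
                     dimnames = list(transcript_id, design$sample_id))
    for (j in seq_len(n_samples)) {
      values[, j] <- baseline + offsets[, trt_idx[j]] + pop_eff[, cell_key[j]]
    }
    values <- values + matrix(rnorm(n_transcripts * n_samples, 0, residual_sd),
                              n_transcripts, n_samples)

    truth <- tibble::tibble(
      transcript_id = transcript_id,
      planted_category = cats,
      direction = ifelse(cats == 0, NA_character_, direction),
      delta_C = offsets[, "C"],
      delta_CDX = offsets[, "CDX"],
      delta_MLX = offsets[, "MLX"]
    )

    list(
      expression = expression_tibble(values, transcript_id),
      truth = truth,
      design = design
    )
  })
}

# matrix -> tidy expression tibble (transcript_id + one column per sample)
expression_tibble <- function(values, transcript_id) {
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(transcript_id = transcript_id), out)
}

#' Convert a tidy expression tibble to a numeric matrix
#'
#' @param expression Tibble with `transcript_id` and one numeric column
#'   per sample.
#' @return Numeric matrix, rownames = transcript ids.
#' @export
expression_matrix <- function(expression) {
  stopifnot("transcript_id" %in% names(expression))
  m <- as.matrix(expression[setdiff(names(expression), "transcript_id")])
  storage.mode(m) <- "double"
  rownames(m) <- expression$transcript_id
  if (any(!is.finite(m))) abort("expression values must all be finite")
  m
}
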