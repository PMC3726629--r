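#' Default pipeline configuration
#'
#' Settings for a full synthetic run of the pipeline, emulating the
#' study design: 3 treatments x 3 populations x 2 replicate arrays,
#' 1000 transcripts with planted categories, 17-tissue annotation
#' panel, 20 vials per population for the fitness and sex-ratio assays.
#'
#' @param seed Integer seed for every stochastic stage.
#' @return Nested list of settings; override fields before passing to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    design = list(n_treatments = 3, n_populations = 3, n_replicates = 2),
    expression = list(
      n_transcripts = 1000,
      category_fractions = c("1" = 0.01, "3" = 0.03, "4" = 0.03),
      effect_size = 1.5, population_sd = 0.1, residual_sd = 0.3
    ),
    annotations = list(tissue_set_fraction = 0.03, sex_bias_prob = 0.5),
    fitness = list(treatment_props = c(C = 0.5, CDX = 0.4, MLX = 0.6),
                   n_vials = 20, offspring_per_vial = 80),
    sex_ratio = list(treatment_props = c(C = 0.5, CDX = 0.45, MLX = 0.55),
                     n_vials = 20, offspring_per_vial = 80),
    de = list(q_star = 0.05, pairwise_alpha = 0.05,
              pairwise_adjust = "none", mode = "strict"),
    enrichment = list(min_category_size = 10)
  )
}

#' Write a pipeline configuration to YAML
#'
#' Named numeric vectors (category fractions, treatment proportions) are
#' stored as YAML maps so their names survive the round trip back
#' through [run_pipeline()].
#'
#' @param config Config list.
#' @param path Output YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  config$expression$category_fractions <-
    as.list(config$expression$category_fractions)
  config$fitness$treatment_props <- as.list(config$fitness$treatment_props)
  config$sex_ratio$treatment_props <-
    as.list(config$sex_ratio$treatment_props)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> differential expression -> category
#' classification -> enrichment -> feminization -> fitness and
#' sex-ratio ANOVAs, deterministically under the config seed.
#' Enrichment batteries (GO, chromosome, tissue, MR-GSE against the
#' three fitness rankings) run only on categories with at least
#' `min_category_size` members, mirroring the practice of reporting
#' enrichment from the well-populated categories only.
#'
#' @param config Config list ([default_pipeline_config()]) or path to a
#'   YAML file with the same structure.
#' @param out_dir Optional directory; when given, every stage writes its
#'   table there (TSV/CSV/JSON) and a `report.json` records the seed and
#'   config hash.
#' @return List of class `mlx_report`: `design`, `expression`, `truth`,
#'   `annotation`, `de`, `category_counts`, `enrichment` (per-category
#'   list of `go`, `chromosome`, `tissue`, `mrgse`), `feminization_X`,
#'   `feminization_autosomes`, `fitness_anova`, `sex_ratio_anova`,
#'   `seed`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  cfg$expression$category_fractions <-
    unlist(cfg$expression$category_fractions)
  cfg$fitness$treatment_props <- unlist(cfg$fitness$treatment_props)
  cfg$sex_ratio$treatment_props <- unlist(cfg$sex_ratio$treatment_props)
  seed <- cfg$seed

  design <- generate_design(cfg$design$n_treatments,
                            cfg$design$n_populations,
                            cfg$design$n_replicates)
  sim <- generate_expression(
    design, cfg$expression$n_transcripts,
    category_fractions = cfg$expression$category_fractions,
    effect_size = cfg$expression$effect_size,
    population_sd = cfg$expression$population_sd,
    residual_sd = cfg$expression$residual_sd,
    seed = seed
  )
  annotation <- generate_annotations(
    cfg$expression$n_transcripts,
    tissue_set_fraction = cfg$annotations$tissue_set_fraction,
    sex_bias_prob = cfg$annotations$sex_bias_prob,
    seed = seed + 1
  )
  fitness <- generate_fitness_assay(
    treatment_props = cfg$fitness$treatment_props,
    n_populations = cfg$design$n_populations,
    n_vials = cfg$fitness$n_vials,
    offspring_per_vial = cfg$fitness$offspring_per_vial,
    seed = seed + 2
  )
  sexratio <- generate_sex_ratio_assay(
    treatment_props = cfg$sex_ratio$treatment_props,
    n_populations = cfg$design$n_populations,
    n_vials = cfg$sex_ratio$n_vials,
    offspring_per_vial = cfg$sex_ratio$offspring_per_vial,
    seed = seed + 3
  )

  de <- de_analysis(sim$expression, design,
                    q_star = cfg$de$q_star,
                    pairwise_alpha = cfg$de$pairwise_alpha,
                    pairwise_adjust = cfg$de$pairwise_adjust,
                    mode = cfg$de$mode)
  counts <- category_counts(de)

  universe <- de$transcript_id
  enr <- list()
  floor_n <- cfg$enrichment$min_category_size
  for (k in 1:6) {
    members <- de$transcript_id[de$category == k]
    if (length(members) < floor_n) next
    enr[[as.character(k)]] <- list(
      go = hypergeom_go(members, universe, annotation),
      chromosome = chrom_chisq(members, annotation, universe),
      tissue = tissue_fisher(members, annotation, universe),
      mrgse = list(
        male_fitness = mr_gse(members,
          stats::setNames(annotation$male_fitness_score,
                          annotation$transcript_id)),
        female_fitness = mr_gse(members,
          stats::setNames(annotation$female_fitness_score,
                          annotation$transcript_id)),
        antagonism = mr_gse(members,
          stats::setNames(annotation$antagonism_score,
                          annotation$transcript_id))
      )
    )
  }

  fem_x <- feminization_test(sim$expression, design, annotation, "X")
  fem_auto <- feminization_test(sim$expression, design, annotation,
                                "autosomes")
  fit_anova <- analyze_assay(fitness, "fitness")
  sr_anova <- analyze_assay(sexratio, "sexratio")

  report <- structure(
    list(design = design, expression = sim$expression, truth = sim$truth,
         annotation = annotation, de = de, category_counts = counts,
         enrichment = enr, feminization_X = fem_x,
         feminization_autosomes = fem_auto, fitness_anova = fit_anova,
         sex_ratio_anova = sr_anova, seed = seed, config = cfg),
    class = "mlx_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mlx_report <- function(x, ...) {
  cat("MLX pipeline report (seed", x$seed, ")\n\n")
  cat("Category counts:\n")
  print(x$category_counts)
  cat(sprintf("\nFitness ANOVA: F(%d, %d) = %.3f, p = %.4f\n",
              x$fitness_anova$df1, x$fitness_anova$df2,
              x$fitness_anova$F, x$fitness_anova$p))
  cat(sprintf("Sex-ratio ANOVA: F(%d, %d) = %.3f, p = %.4f\n",
              x$sex_ratio_anova$df1, x$sex_ratio_anova$df2,
              x$sex_ratio_anova$F, x$sex_ratio_anova$p))
  cat(sprintf("Feminization (X): X2 = %.3f, df = %d, p = %.4g\n",
              x$feminization_X$statistic, x$feminization_X$df,
              x$feminization_X$p))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_design_csv(report$design, p("design.csv"))
  write_expression_tsv(report$expression, p("expression.tsv"))
  readr::write_csv(report$truth, p("truth.csv"))
  write_annotation_csv(report$annotation, p("annotation.csv"))
  readr::write_tsv(tibble::as_tibble(report$de), p("de_results.tsv"))
  readr::write_csv(report$category_counts, p("category_counts.csv"))
  for (k in names(report$enrichment)) {
    e <- report$enrichment[[k]]
    readr::write_tsv(e$go, p(sprintf("enrichment_go_cat%s.tsv", k)))
    readr::write_tsv(e$tissue, p(sprintf("enrichment_tissue_cat%s.tsv", k)))
    readr::write_tsv(e$chromosome$table,
                     p(sprintf("enrichment_chrom_cat%s.tsv", k)))
  }
  cfg_hash <- digest_config(report$config)
  summary <- list(
    seed = report$seed,
    config_hash = cfg_hash,
    category_counts = stats::setNames(as.list(report$category_counts$n),
                                      report$category_counts$category),
    fitness_anova = unclass(glance(report$fitness_anova)),
    sex_ratio_anova = unclass(glance(report$sex_ratio_anova)),
    feminization_X = list(
      observed = as.list(report$feminization_X$observed),
      expected = unname(report$feminization_X$expected[1]),
      statistic = report$feminization_X$statistic,
      df = report$feminization_X$df,
      p = report$feminization_X$p
    ),
    feminization_autosomes = list(
      statistic = report$feminization_autosomes$statistic,
      df = report$feminization_autosomes$df,
      p = report$feminization_autosomes$p
    )
  )
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Small stable config fingerprint (no external digest dependency).
digest_config <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
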