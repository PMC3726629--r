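#' @importFrom rlang .data abort warn .env
#' @importFrom stats rnorm rbinom rbeta runif pf pt phyper fisher.test
#'   p.adjust pchisq pnorm pwilcox asin sd quantile
NULL

# Treatment levels, in the conventional reporting order.
TREATMENTS <- c("C", "CDX", "MLX")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL leaves the RNG alone.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Check a design tibble has the expected columns and unique triples.
validate_design <- function(design) {
  needed <- c("sample_id", "treatment", "population", "replicate")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  key <- paste(design$treatment, design$population, design$replicate)
  if (anyDuplicated(key)) {
    abort("design has duplicated (treatment, population, replicate) triples")
  }
  invisible(design)
}
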