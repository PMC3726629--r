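#' Read and write pipeline tables
#'
#' Plain-text interchange formats: the expression matrix as TSV
#' (transcripts in rows, header = sample ids, first column
#' `transcript_id`), the design and vial tables as CSV, annotations as
#' CSV with `go_terms` / `tissue_specific_in` collapsed into
#' `;`-separated strings, rankings as two-column TSV.
#'
#' @param expression Expression tibble.
#' @param path File path.
#' @name mlx_io
NULL

#' @rdname mlx_io
#' @export
write_expression_tsv <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' @rdname mlx_io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname mlx_io
#' @param design Design tibble.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname mlx_io
#' @export
read_design_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  d$treatment <- factor(d$treatment,
                        levels = intersect(TREATMENTS, unique(d$treatment)))
  validate_design(d)
}

#' @rdname mlx_io
#' @param annotation Annotation tibble.
#' @export
write_annotation_csv <- function(annotation, path) {
  flat <- dplyr::mutate(
    annotation,
    go_terms = vapply(.data$go_terms, paste, character(1), collapse = ";"),
    tissue_specific_in = vapply(.data$tissue_specific_in, paste,
                                character(1), collapse = ";")
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname mlx_io
#' @export
read_annotation_csv <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE)
  split_col <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  flat$go_terms <- split_col(flat$go_terms)
  flat$tissue_specific_in <- split_col(flat$tissue_specific_in)
  flat$chromosome <- as.character(flat$chromosome)
  flat
}
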