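#' Read and write the tab-separated dialects used across the package
#'
#' All tables travel as plain TSV with headers. Coordinates are stored
#' 0-based half-open (BED convention); 1-based inclusive input is accepted
#' via `dialect = "one_based"` and converted on read.
#'
#' @name cnvburden-io
NULL

shift_coords <- function(df, dialect) {
  if (dialect == "one_based") df$start <- df$start - 1
  df
}

#' @rdname cnvburden-io
#' @param file Path to a TSV file.
#' @param dialect `"bed"` (0-based half-open, default) or `"one_based"`
#'   (1-based inclusive, converted on read).
#' @return A tibble.
#' @export
read_cnv_calls <- function(file, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(file, show_col_types = FALSE)
  if ("name" %in% names(df) && !"cnv_class" %in% names(df)) {
    # BED-style name field carrying "class:algorithm"
    parts <- strsplit(df$name, ":", fixed = TRUE)
    df$cnv_class <- vapply(parts, `[`, "", 1)
    df$algorithm <- vapply(parts, `[`, "", 2)
    df$name <- NULL
  }
  df <- shift_coords(df, dialect)
  validate_calls(df)
  df
}

#' @rdname cnvburden-io
#' @export
read_sample_sheet <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE)
  need <- c("sample_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad) > 0) abort("status must be 'case' or 'control'")
  df
}

#' @rdname cnvburden-io
#' @export
read_hbd_segments <- function(file, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(file, show_col_types = FALSE)
  df <- shift_coords(df, dialect)
  validate_intervals(df, "HBD segment table")
  df
}

#' @rdname cnvburden-io
#' @export
read_genome_manifest <- function(file) {
  validate_genome(readr::read_tsv(file, show_col_types = FALSE))
}

#' @rdname cnvburden-io
#' @export
read_segdup_pairs <- function(file, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(file, show_col_types = FALSE)
  if (dialect == "one_based") {
    df$start_a <- df$start_a - 1
    df$start_b <- df$start_b - 1
  }
  need <- c("chrom", "start_a", "end_a", "start_b", "end_b")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("segdup table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if ("homology" %in% names(df) &&
      any(df$homology < 0 | df$homology > 1)) {
    abort("homology must be a fraction in [0, 1]")
  }
  df
}

#' @rdname cnvburden-io
#' @export
read_variants <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE)
}

#' @rdname cnvburden-io
#' @param x Tibble to write.
#' @export
write_tsv_table <- function(x, file) {
  drop <- vapply(x, is.list, TRUE)  # list-columns are in-memory only
  readr::write_tsv(x[, !drop], file)
  invisible(file)
}
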