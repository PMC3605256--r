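#' Multi-algorithm consensus of CNV calls
#'
#' Copy-number calls from SNP arrays are typically made by several
#' independent algorithms with only partial concordance; calls supported by
#' at least `min_algorithms` distinct algorithms are retained (the classic
#' "2 of 3" rule). Within each sample, platform, chromosome and CNV class,
#' calls are grouped greedily in start order: a seed call absorbs later
#' calls from algorithms not yet represented whose reciprocal overlap with
#' *every* current group member is at least `ro_threshold`. A group with
#' enough distinct algorithms becomes one consensus call whose span is the
#' intersection of its members (conservative); the union span is kept as
#' metadata.
#'
#' @param calls Tibble of per-algorithm calls with columns `sample_id`,
#'   `chrom`, `start`, `end`, `cnv_class` (`"gain"`/`"loss"`), `algorithm`
#'   and optionally `platform`.
#' @param min_algorithms Minimum number of distinct supporting algorithms.
#' @param ro_threshold Reciprocal-overlap threshold for two calls to count
#'   as the same event.
#' @return Tibble of consensus calls: `sample_id`, `platform`, `chrom`,
#'   `start`, `end` (intersection span), `union_start`, `union_end`,
#'   `cnv_class`, `n_algorithms`, `algorithms`.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   sample_id = "s1", chrom = "chr1", start = c(100, 110, 5000),
#'   end = c(1100, 1050, 6000), cnv_class = "loss",
#'   algorithm = c("gada", "penncnv", "quantisnp"), platform = "illumina370k"
#' )
#' consensus_merge(calls)
consensus_merge <- function(calls, min_algorithms = 2, ro_threshold = 0.5) {
  stopifnot(min_algorithms >= 1, ro_threshold > 0, ro_threshold <= 1)
  if (nrow(calls) == 0) return(empty_consensus())
  validate_calls(calls)
  if (!"platform" %in% names(calls)) calls$platform <- "array"

  dup <- duplicated(calls[, c("sample_id", "algorithm", "chrom",
                              "start", "end", "cnv_class")])
  if (any(dup)) {
    abort("duplicate (sample, algorithm, interval) rows in call table")
  }

  calls |>
    dplyr::group_by(.data$sample_id, .data$platform, .data$chrom, .data$cnv_class) |>
    dplyr::group_modify(~ consensus_group(.x, min_algorithms, ro_threshold)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "platform", "chrom", "start", "end",
                  "union_start", "union_end", "cnv_class",
                  "n_algorithms", "algorithms") |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start)
}

validate_calls <- function(calls) {
  need <- c("sample_id", "chrom", "start", "end", "cnv_class", "algorithm")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    abort(paste0("call table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_intervals(calls, "call table")
  bad <- setdiff(unique(calls$cnv_class), c("gain", "loss"))
  if (length(bad) > 0) {
    abort(paste0("cnv_class must be 'gain' or 'loss', got: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(calls$algorithm))) abort("empty algorithm label")
  invisible(calls)
}

empty_consensus <- function() {
  tibble::tibble(
    sample_id = character(), platform = character(), chrom = character(),
    start = numeric(), end = numeric(),
    union_start = numeric(), union_end = numeric(),
    cnv_class = character(), n_algorithms = integer(), algorithms = character()
  )
}

# greedy all-pairs grouping within one (sample, platform, chrom, class) slice
consensus_group <- function(x, min_algorithms, ro_threshold) {
  x <- dplyr::arrange(x, .data$start, .data$end, .data$algorithm)
  n <- nrow(x)
  assigned <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- i
    assigned[i] <- TRUE
    for (j in seq_len(n)) {
      if (assigned[j] || x$algorithm[j] %in% x$algorithm[members]) next
      ro <- reciprocal_overlap(x$start[members], x$end[members],
                               x$start[j], x$end[j])
      if (all(ro >= ro_threshold)) {
        members <- c(members, j)
        assigned[j] <- TRUE
      }
    }
    if (length(members) >= min_algorithms) {
      out[[length(out) + 1]] <- tibble::tibble(
        start = max(x$start[members]),
        end = min(x$end[members]),
        union_start = min(x$start[members]),
        union_end = max(x$end[members]),
        n_algorithms = length(members),
        algorithms = paste(sort(x$algorithm[members]), collapse = ",")
      )
    }
  }
  if (length(out) == 0) {
    tibble::tibble(start = numeric(), end = numeric(),
                   union_start = numeric(), union_end = numeric(),
                   n_algorithms = integer(), algorithms = character())
  } else {
    dplyr::bind_rows(out)
  }
}
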