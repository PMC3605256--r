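#' Cluster consensus calls into CNV regions
#'
#' Combines calls made across samples on one platform into copy-number
#' variable regions (CNVRs) using a reciprocal-overlap threshold, and
#' annotates each region with its cohort-wide frequency: the proportion of
#' *all* samples in `samples` (cases and controls together) carrying the
#' region. Gains and losses never merge.
#'
#' Clustering is single-linkage and seeded: within each chromosome and CNV
#' class, calls are sorted by start; the first unassigned call seeds a
#' region, and any unassigned call with reciprocal overlap at least
#' `ro_threshold` against the current region envelope is absorbed (growing
#' the envelope), iterating until no further call joins. The procedure is
#' deterministic given the sort order.
#'
#' @param calls Consensus-call tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `cnv_class`; output of [consensus_merge()] works directly).
#' @param samples Sample sheet tibble with `sample_id`; its row count is the
#'   frequency denominator, so pass the full case+control set genotyped on
#'   the platform being clustered.
#' @param ro_threshold Reciprocal-overlap threshold in `(0, 1]`.
#' @return Tibble with one row per region: `region_id`, `chrom`, `start`,
#'   `end` (envelope), `cnv_class`, `n_calls`, `n_carriers`, `frequency`,
#'   plus a list-column `carrier_samples`.
#' @export
cluster_cnvrs <- function(calls, samples, ro_threshold = 0.5) {
  stopifnot(ro_threshold > 0, ro_threshold <= 1)
  if (nrow(calls) == 0) return(empty_regions())
  need <- c("sample_id", "chrom", "start", "end", "cnv_class")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    abort(paste0("call table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_intervals(calls, "call table")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in sample sheet")
  n_total <- nrow(samples)
  if (n_total == 0) abort("empty sample sheet")

  regions <- calls |>
    dplyr::group_by(.data$chrom, .data$cnv_class) |>
    dplyr::group_modify(~ cluster_slice(.x, ro_threshold)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start, .data$cnv_class)

  regions |>
    dplyr::mutate(
      region_id = sprintf("cnvr_%04d", dplyr::row_number()),
      n_carriers = purrr::map_int(.data$carrier_samples, length),
      frequency = .data$n_carriers / n_total
    ) |>
    dplyr::select("region_id", "chrom", "start", "end", "cnv_class",
                  "n_calls", "n_carriers", "frequency", "carrier_samples")
}

empty_regions <- function() {
  tibble::tibble(
    region_id = character(), chrom = character(),
    start = numeric(), end = numeric(), cnv_class = character(),
    n_calls = integer(), n_carriers = integer(), frequency = numeric(),
    carrier_samples = list()
  )
}

# single-linkage seeded clustering of one (chrom, class) slice
cluster_slice <- function(x, ro_threshold) {
  x <- dplyr::arrange(x, .data$start, .data$end, .data$sample_id)
  n <- nrow(x)
  assigned <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- i
    assigned[i] <- TRUE
    env_s <- x$start[i]; env_e <- x$end[i]
    repeat {
      cand <- which(!assigned)
      if (length(cand) == 0) break
      ro <- reciprocal_overlap(env_s, env_e, x$start[cand], x$end[cand])
      hit <- cand[ro >= ro_threshold]
      if (length(hit) == 0) break
      members <- c(members, hit)
      assigned[hit] <- TRUE
      env_s <- min(env_s, x$start[hit])
      env_e <- max(env_e, x$end[hit])
    }
    out[[length(out) + 1]] <- tibble::tibble(
      start = env_s, end = env_e,
      n_calls = length(members),
      carrier_samples = list(sort(unique(x$sample_id[members])))
    )
  }
  dplyr::bind_rows(out)
}

#' Filter CNV regions to rare events
#'
#' Retains regions with frequency strictly below `max_freq` (the "less than
#' 5%" convention), envelope length at least `min_size`, and optionally a
#' single CNV class. Idempotent; its output is always a subset of its input.
#'
#' @param regions Output of [cluster_cnvrs()] (any tibble with `frequency`,
#'   `start`, `end` and `cnv_class` columns).
#' @param max_freq Exclusive upper bound on region frequency.
#' @param min_size Inclusive lower bound on envelope length in bp.
#' @param cnv_class Optional `"gain"` or `"loss"` restriction.
#' @return Filtered tibble.
#' @export
filter_rare <- function(regions, max_freq = 0.05, min_size = 0,
                        cnv_class = NULL) {
  out <- dplyr::filter(
    regions,
    .data$frequency < max_freq,
    .data$end - .data$start >= min_size
  )
  if (!is.null(cnv_class)) {
    cls <- cnv_class
    out <- dplyr::filter(out, .data$cnv_class == cls)
  }
  out
}
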