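#' Remove HBD segments that are deletion artifacts
#'
#' Hidden-Markov HBD callers read a large hemizygous deletion as a run of
#' homozygosity, because the remaining single allele genotypes as
#' homozygous at every probe. Segments whose reciprocal overlap with a
#' same-sample deletion call reaches `ro_threshold` are therefore removed
#' before inbreeding analysis.
#'
#' @param segments HBD segment tibble (`sample_id`, `chrom`, `start`,
#'   `end`).
#' @param deletions Consensus deletion calls for the same samples
#'   (`sample_id`, `chrom`, `start`, `end`, optionally `cnv_class`; only
#'   `"loss"` rows are used when the column is present).
#' @param ro_threshold Reciprocal-overlap threshold for calling a segment
#'   an artifact.
#' @return List with tibbles `kept` and `removed`; `removed` carries the
#'   matched deletion span and `segment_bp` sizes. Their union is exactly
#'   the input.
#' @export
filter_deletion_artifacts <- function(segments, deletions, ro_threshold = 0.5) {
  validate_intervals(segments, "HBD segment table")
  if ("cnv_class" %in% names(deletions)) {
    deletions <- dplyr::filter(deletions, .data$cnv_class == "loss")
  }
  if (nrow(segments) == 0 || nrow(deletions) == 0) {
    return(list(kept = segments,
                removed = dplyr::mutate(segments[0, ], segment_bp = numeric())))
  }
  validate_intervals(deletions, "deletion table")
  is_artifact <- purrr::pmap_lgl(
    list(segments$sample_id, segments$chrom, segments$start, segments$end),
    function(sid, chrom, s, e) {
      d <- deletions[deletions$sample_id == sid & deletions$chrom == chrom, ]
      nrow(d) > 0 &&
        any(reciprocal_overlap(s, e, d$start, d$end) >= ro_threshold)
    }
  )
  list(
    kept = segments[!is_artifact, ],
    removed = dplyr::mutate(segments[is_artifact, ],
                            segment_bp = .data$end - .data$start)
  )
}

# normalize segments: clip to manifest, merge overlaps within sample x chrom
normalize_segments <- function(segments, genome) {
  validate_genome(genome)
  segments |>
    dplyr::inner_join(genome, by = "chrom") |>
    dplyr::mutate(start = pmax(.data$start, 0),
                  end = pmin(.data$end, .data$length)) |>
    dplyr::filter(.data$end > .data$start) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::reframe(tibble::as_tibble(merge_interval_runs(.data$start, .data$end)))
}

#' Segment-based inbreeding coefficient
#'
#' Estimates each sample's inbreeding coefficient F as the fraction of the
#' autosomal genome covered by homozygous-by-descent segments: total
#' autosomal HBD length (segments at least `min_segment` long, after
#' clipping to the manifest and merging overlaps) divided by total
#' autosomal manifest length. Sex chromosomes are excluded (the male X is
#' hemizygous).
#'
#' @param segments HBD segment tibble (`sample_id`, `chrom`, `start`, `end`).
#' @param genome Genome manifest.
#' @param min_segment Minimum segment length (bp) counted towards F.
#' @param samples Optional sample sheet; when given, samples without
#'   segments get explicit `f_hat = 0` rows.
#' @return Tibble `sample_id`, `f_hat`, `n_segments`, `hbd_bp`, `genome_bp`.
#' @export
inbreeding_coefficient <- function(segments, genome = toy_genome(),
                                   min_segment = 0, samples = NULL) {
  validate_genome(genome)
  autosomes <- genome$chrom[compartment_of(genome$chrom, genome) == "autosome"]
  if (length(autosomes) == 0) abort("manifest contains no autosomes")
  denom <- sum(genome$length[genome$chrom %in% autosomes])

  norm <- normalize_segments(
    dplyr::filter(segments, .data$chrom %in% autosomes), genome
  ) |>
    dplyr::filter(.data$end - .data$start >= min_segment)

  prof <- norm |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      hbd_bp = sum(.data$end - .data$start),
      .groups = "drop"
    )
  if (!is.null(samples)) {
    prof <- samples |>
      dplyr::select("sample_id") |>
      dplyr::left_join(prof, by = "sample_id") |>
      dplyr::mutate(n_segments = dplyr::coalesce(.data$n_segments, 0L),
                    hbd_bp = dplyr::coalesce(.data$hbd_bp, 0))
  }
  dplyr::mutate(prof, genome_bp = denom, f_hat = .data$hbd_bp / denom) |>
    dplyr::select("sample_id", "f_hat", "n_segments", "hbd_bp", "genome_bp")
}

#' Threshold classification of inbreeding coefficients
#'
#' Flags samples whose F strictly exceeds each threshold of the
#' conventional ladder (0.5%, 1.6% and 6.25% -- the last being the
#' first-cousin expectation of 1/16).
#'
#' @param profiles Output of [inbreeding_coefficient()].
#' @param thresholds Numeric vector of strict lower bounds on F.
#' @return `profiles` with one logical column per threshold
#'   (`f_gt_0.5pct`, ...).
#' @export
classify_f <- function(profiles, thresholds = c(0.005, 0.016, 0.0625)) {
  for (th in thresholds) {
    nm <- paste0("f_gt_", formatC(th * 100, format = "fg"), "pct")
    profiles[[nm]] <- profiles$f_hat > th
  }
  profiles
}

#' Flag whole-chromosome homozygosity (uniparental isodisomy)
#'
#' A chromosome almost entirely covered by HBD segments in one sample is
#' the signature of uniparental isodisomy. Coverage is the merged segment
#' length divided by the manifest chromosome length.
#'
#' @param segments HBD segment tibble.
#' @param genome Genome manifest.
#' @param coverage_threshold Minimum covered fraction to flag (default 0.9).
#' @return Tibble `sample_id`, `chrom`, `covered_fraction` for flagged
#'   pairs only.
#' @export
detect_upd <- function(segments, genome = toy_genome(),
                       coverage_threshold = 0.9) {
  if (nrow(segments) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          covered_fraction = numeric()))
  }
  normalize_segments(segments, genome) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::summarise(covered_bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::inner_join(genome, by = "chrom") |>
    dplyr::mutate(covered_fraction = .data$covered_bp / .data$length) |>
    dplyr::filter(.data$covered_fraction >= coverage_threshold) |>
    dplyr::select("sample_id", "chrom", "covered_fraction")
}

#' Association between inbreeding and case status
#'
#' Logistic regression of case/control status on inbreeding, either on the
#' continuous coefficient F or on a categorical indicator `F > threshold`,
#' optionally adjusting for ancestry covariates. Reuses the burden
#' regression machinery, including separation flagging.
#'
#' @param profiles Output of [inbreeding_coefficient()].
#' @param samples Sample sheet with `sample_id`, `status` and any covariate
#'   columns.
#' @param mode `"continuous"` (regress on F) or `"categorical"` (regress on
#'   the indicator `F > threshold`).
#' @param threshold Threshold for categorical mode.
#' @param covariates Covariate column names in `samples`.
#' @param engine Passed to [logistic_burden()].
#' @return A `burden_fit`.
#' @export
inbreeding_association <- function(profiles, samples,
                                   mode = c("continuous", "categorical"),
                                   threshold = 0.0625,
                                   covariates = character(),
                                   engine = c("ml", "firth")) {
  mode <- match.arg(mode)
  df <- dplyr::inner_join(samples, profiles, by = "sample_id")
  if (mode == "categorical") {
    df$inbreeding <- as.numeric(df$f_hat > threshold)
  } else {
    df$inbreeding <- df$f_hat
  }
  fit <- logistic_burden(df, burden_col = "inbreeding",
                         covariates = covariates, engine = engine)
  fit$term <- paste0("inbreeding_", mode)
  fit
}
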