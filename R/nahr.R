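#' Classify calls as candidate NAHR events
#'
#' Non-allelic homologous recombination (NAHR) between paralogous segmental
#' duplications generates recurrent rearrangements whose breakpoints fall
#' inside the duplicons. A call is classified as a candidate NAHR event when
#' it is at least `min_size` long and its two breakpoints each lie within
#' (plus/minus `slack`) one member of the same homologous duplication pair
#' on the same chromosome, in either orientation.
#'
#' The default `slack` of 20 kb reflects breakpoint uncertainty from typical
#' SNP-array probe spacing.
#'
#' @param calls Call tibble with `chrom`, `start`, `end`.
#' @param segdups Segmental-duplication pair tibble with columns `chrom`,
#'   `start_a`, `end_a`, `start_b`, `end_b` and optionally `homology`.
#' @param min_size Minimum call length (bp) to be considered.
#' @param slack Breakpoint tolerance in bp around each duplicon.
#' @param min_homology Optional minimum pair homology; pairs below it are
#'   ignored (requires a `homology` column).
#' @return `calls` with an added logical column `nahr`.
#' @export
classify_nahr <- function(calls, segdups, min_size = 1e5, slack = 2e4,
                          min_homology = NULL) {
  validate_intervals(calls, "call table")
  need <- c("chrom", "start_a", "end_a", "start_b", "end_b")
  miss <- setdiff(need, names(segdups))
  if (length(miss) > 0) {
    abort(paste0("segdup table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.null(min_homology)) {
    segdups <- dplyr::filter(segdups, .data$homology >= min_homology)
  }
  within_dup <- function(pos, s, e) pos >= s - slack & pos <= e + slack
  flag <- function(chrom, start, end) {
    if (end - start < min_size) return(FALSE)
    sd <- segdups[segdups$chrom == chrom, ]
    if (nrow(sd) == 0) return(FALSE)
    fwd <- within_dup(start, sd$start_a, sd$end_a) &
      within_dup(end, sd$start_b, sd$end_b)
    rev <- within_dup(start, sd$start_b, sd$end_b) &
      within_dup(end, sd$start_a, sd$end_a)
    any(fwd | rev)
  }
  calls$nahr <- purrr::pmap_lgl(
    list(calls$chrom, calls$start, calls$end), flag
  )
  calls
}
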