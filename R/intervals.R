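#' Reciprocal overlap of genomic intervals
#'
#' The symmetric interval similarity used to decide whether two copy-number
#' calls describe the same event: the length of the intersection divided by
#' the length of the *larger* interval, i.e.
#' `min(overlap / len(a), overlap / len(b))`. Intervals are 0-based
#' half-open. Intervals on different chromosomes have overlap 0.
#'
#' @param start1,end1,start2,end2 Numeric vectors of interval coordinates
#'   (recycled to a common length). Each interval must satisfy `end > start`.
#' @param chrom1,chrom2 Optional chromosome labels; when supplied, pairs on
#'   different chromosomes get overlap 0.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' reciprocal_overlap(0, 100, 50, 150) # 0.5
#' reciprocal_overlap(0, 100, 90, 490) # 0.025
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  if (any(end1 <= start1) || any(end2 <= start2)) {
    abort("malformed interval: end must be greater than start")
  }
  ovl <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  ro <- pmin(ovl / (end1 - start1), ovl / (end2 - start2))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    ro[chrom1 != chrom2] <- 0
  }
  ro
}

# overlap length (bp) between one interval and a vector of intervals
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

validate_intervals <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(df$end <= df$start)) {
    abort(paste0(what, ": malformed interval (end <= start)"))
  }
  invisible(df)
}

# merge overlapping/abutting [start, end) intervals within a sorted frame;
# returns merged start/end vectors
merge_interval_runs <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) == 0) return(list(start = start, end = end))
  grp <- cumsum(c(TRUE, start[-1] > cummax(end)[-length(end)]))
  list(
    start = as.numeric(tapply(start, grp, min)),
    end = as.numeric(tapply(end, grp, max))
  )
}
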