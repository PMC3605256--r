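#' Forest plot of per-cohort and combined burden estimates
#'
#' @param fits Named list of `burden_fit` objects (per cohort).
#' @param combined Optional `burden_meta` from [combine_cohorts()].
#' @return A ggplot.
#' @export
plot_burden_forest <- function(fits, combined = NULL) {
  rows <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(tidy(f), cohort = nm)
  })
  if (!is.null(combined)) {
    rows <- dplyr::bind_rows(
      rows, dplyr::mutate(tidy(combined), cohort = "combined")
    )
  }
  rows$cohort <- factor(rows$cohort, levels = rev(unique(rows$cohort)))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$odds.ratio, y = .data$cohort)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio per event (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.burden_meta <- function(object, ...) {
  fits <- object$cohort_fits
  if (is.null(fits)) fits <- list(combined = object)
  nm <- names(fits) %||% paste0("cohort", seq_along(fits))
  names(fits) <- nm
  plot_burden_forest(fits, combined = if (!is.null(object$cohort_fits)) object)
}

#' Length distribution of HBD segments
#'
#' The hallmark L-shaped distribution: many short background tracts, a
#' tail of long autozygous segments, and any whole-chromosome events at
#' the extreme.
#'
#' @param segments HBD segment tibble.
#' @param bins Histogram bin count.
#' @return A ggplot.
#' @export
plot_hbd_lengths <- function(segments, bins = 40) {
  df <- dplyr::mutate(segments, length_mb = (.data$end - .data$start) / 1e6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_mb)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "segment length (Mb, log scale)", y = "segments") +
    ggplot2::theme_minimal()
}

#' Two-dimensional variant prioritisation plot
#'
#' Individual Score against Population Score for a ranked exome; the
#' top-ranked variant is highlighted.
#'
#' @param scored Output of [score_variants()] / [rank_variants()].
#' @param highlight Number of top-ranked variants to label.
#' @return A ggplot.
#' @export
plot_variant_scores <- function(scored, highlight = 1) {
  top <- head(scored[order(scored$rank), ], highlight)
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$p_ind, y = .data$p_pop)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = top, colour = "red", size = 2) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$variant_id),
                       vjust = -1, size = 3, colour = "red") +
    ggplot2::labs(x = "Individual Score", y = "Population Score") +
    ggplot2::theme_minimal()
}
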