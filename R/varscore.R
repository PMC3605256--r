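#' Default normalization specification for the five annotators
#'
#' The two-dimensional prioritisation score sums normalized predictions of
#' functional impact from five commonly used annotation algorithms:
#' phyloP and GERP (conservation), PolyPhen2 and SIFT (protein impact) and
#' LRT (likelihood ratio). Each raw score is mapped affinely onto `[0, 1]`
#' with 1 = most damaging; SIFT is direction-flipped (low SIFT = damaging).
#' The ranges here are the annotators' conventional theoretical ranges and
#' are configuration, not code: pass a modified tibble to change them.
#'
#' @return Tibble with columns `annotator`, `min`, `max`, `direction`
#'   (`"ascending"` = high raw is damaging, `"descending"` = low raw is
#'   damaging).
#' @export
default_normalization <- function() {
  tibble::tribble(
    ~annotator,  ~min,   ~max,  ~direction,
    "phylop",    -14,    6,     "ascending",
    "polyphen2", 0,      1,     "ascending",
    "sift",      0,      1,     "descending",
    "gerp",      -12.3,  6.17,  "ascending",
    "lrt",       0,      1,     "ascending"
  )
}

#' Normalize raw annotation scores onto \[0, 1\]
#'
#' Affinely rescales each annotator column to `[0, 1]` with higher = more
#' damaging, flipping descending annotators. Raw values outside the
#' declared range are clamped (with a message); missing values are treated
#' as 0 after normalization (benign) under `na_action = "zero"`, or the
#' variant is dropped under `na_action = "drop"`.
#'
#' @param variants Variant tibble carrying one column per annotator named
#'   in `spec`.
#' @param spec Normalization spec, see [default_normalization()].
#' @param na_action `"zero"` (default) or `"drop"`.
#' @return `variants` with added `norm_<annotator>` columns.
#' @export
normalize_scores <- function(variants, spec = default_normalization(),
                             na_action = c("zero", "drop")) {
  na_action <- match.arg(na_action)
  miss <- setdiff(spec$annotator, names(variants))
  if (length(miss) > 0) {
    abort(paste0("variant table lacks annotator column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (na_action == "drop") {
    before <- nrow(variants)
    variants <- variants[complete.cases(variants[, spec$annotator]), ]
    if (nrow(variants) < before) {
      inform(paste0("dropped ", before - nrow(variants),
                    " variant(s) with missing annotator values"))
    }
  }
  n_clamped <- 0L
  for (i in seq_len(nrow(spec))) {
    ann <- spec$annotator[i]
    raw <- variants[[ann]]
    out_of_range <- sum(raw < spec$min[i] | raw > spec$max[i], na.rm = TRUE)
    n_clamped <- n_clamped + out_of_range
    v <- pmin(pmax(raw, spec$min[i]), spec$max[i])
    v <- (v - spec$min[i]) / (spec$max[i] - spec$min[i])
    if (spec$direction[i] == "descending") v <- 1 - v
    v[is.na(v)] <- 0
    variants[[paste0("norm_", ann)]] <- v
  }
  if (n_clamped > 0) {
    inform(paste0("clamped ", n_clamped, " raw score(s) to their declared range"))
  }
  variants
}

#' Ploidy-weighted Individual Score
#'
#' `p_ind = ploidy x sum(normalized scores)`: the sum of the five
#' normalized deleteriousness predictions, doubled for a homozygous
#' genotype (ploidy 2) relative to a heterozygous one (ploidy 1). Ranges
#' over `[0, 10]`.
#'
#' @param variants Output of [normalize_scores()], with a `ploidy` column
#'   in `{1, 2}`.
#' @param spec Normalization spec naming the annotators summed.
#' @return `variants` with an added `p_ind` column.
#' @export
individual_score <- function(variants, spec = default_normalization()) {
  cols <- paste0("norm_", spec$annotator)
  miss <- setdiff(cols, names(variants))
  if (length(miss) > 0) abort("run normalize_scores() first")
  if (!all(variants$ploidy %in% c(1, 2))) abort("ploidy must be 1 or 2")
  variants$p_ind <- variants$ploidy * rowSums(variants[, cols])
  variants
}

#' Gene-wise maximum Individual Score in a reference panel
#'
#' Scores every panel variant and records, per gene, the maximum
#' Individual Score observed in the population panel (`p_max`). Genes
#' absent from the panel map to 0, so variants in genes with no known
#' population variation keep their full Individual Score as Population
#' Score. Panel genotypes supply the ploidy where available; otherwise
#' heterozygosity (ploidy 1) is assumed.
#'
#' @param panel Panel variant tibble with `gene`, annotator columns and
#'   optionally `ploidy`.
#' @param spec Normalization spec.
#' @return Tibble `gene`, `p_max`.
#' @export
build_gene_max <- function(panel, spec = default_normalization()) {
  if (!"ploidy" %in% names(panel)) panel$ploidy <- 1
  panel |>
    normalize_scores(spec) |>
    individual_score(spec) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(p_max = max(.data$p_ind), .groups = "drop")
}

#' Population Score
#'
#' `p_pop = p_ind - p_max(gene)`: the Individual Score rescaled by the most
#' damaging variation already segregating in the population at the same
#' gene. May be negative; a variant present verbatim in the panel as its
#' gene's maximum scores exactly 0.
#'
#' @param variants Scored variant tibble with `gene` and `p_ind`.
#' @param gene_max Output of [build_gene_max()].
#' @return `variants` with added `p_max` and `p_pop` columns.
#' @export
population_score <- function(variants, gene_max) {
  variants |>
    dplyr::left_join(gene_max, by = "gene") |>
    dplyr::mutate(p_max = dplyr::coalesce(.data$p_max, 0),
                  p_pop = .data$p_ind - .data$p_max)
}

#' Filter variants by minor allele frequency in two reference panels
#'
#' Keeps variants strictly below `max_maf` in *both* reference frequency
#' columns (default: under 10% in each). Missing frequencies are treated
#' as 0 (unobserved), with a message.
#'
#' @param variants Variant tibble with `maf_panel_1` and `maf_panel_2`.
#' @param max_maf Exclusive upper bound applied to both columns.
#' @return Filtered tibble.
#' @export
maf_filter <- function(variants, max_maf = 0.10) {
  need <- c("maf_panel_1", "maf_panel_2")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    abort(paste0("variant table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  n_na <- sum(is.na(variants$maf_panel_1)) + sum(is.na(variants$maf_panel_2))
  if (n_na > 0) inform(paste0(n_na, " missing MAF value(s) treated as 0"))
  m1 <- dplyr::coalesce(variants$maf_panel_1, 0)
  m2 <- dplyr::coalesce(variants$maf_panel_2, 0)
  variants[m1 < max_maf & m2 < max_maf, ]
}

#' Rank variants on the two-dimensional score
#'
#' Total order: descending Population Score, then descending Individual
#' Score, then lexicographic `variant_id` as a deterministic tie-break.
#'
#' @param variants Scored tibble with `p_pop`, `p_ind`, `variant_id`.
#' @return `variants` reordered, with an added `rank` column.
#' @export
rank_variants <- function(variants) {
  out <- dplyr::arrange(variants, dplyr::desc(.data$p_pop),
                        dplyr::desc(.data$p_ind), .data$variant_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Score and rank a subject exome against a reference panel
#'
#' Convenience pipeline: MAF-filter the subject variants, normalize and
#' score them, build the gene-wise panel maxima, attach Population Scores
#' and rank.
#'
#' @param subject Subject variant tibble (`variant_id`, `gene`, `ploidy`,
#'   annotator columns, `maf_panel_1`, `maf_panel_2`).
#' @param panel Reference panel variant tibble.
#' @param spec Normalization spec.
#' @param max_maf MAF cutoff applied to the subject variants.
#' @return Ranked scored tibble.
#' @export
score_variants <- function(subject, panel, spec = default_normalization(),
                           max_maf = 0.10) {
  gene_max <- build_gene_max(panel, spec)
  subject |>
    maf_filter(max_maf) |>
    normalize_scores(spec) |>
    individual_score(spec) |>
    population_score(gene_max) |>
    rank_variants()
}
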