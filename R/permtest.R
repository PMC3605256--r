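#' Permutation test for locus-level carrier association
#'
#' Locus-by-locus association by label permutation. The statistic at each
#' locus is the number of case carriers. Nominal p-values are
#' `(1 + #{permuted statistic >= observed}) / (n_perm + 1)`; genomewide
#' corrected p-values use the max-T rule (the maximum statistic across loci
#' in each permutation), which controls family-wise error under the
#' complete null. Labels are shuffled within cohort by default, preserving
#' platform/cohort composition.
#'
#' @param carriers Logical or 0/1 matrix, samples x loci, with rownames
#'   matching `samples$sample_id` (column names are locus ids).
#' @param samples Sample sheet with `sample_id`, `status` and (when
#'   stratifying) `cohort`.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional integer seed for reproducible permutations.
#' @param stratify `"cohort"` (default) or `"none"`.
#' @return Tibble: `locus_id`, `case_carriers`, `control_carriers`,
#'   `p_nominal`, `p_corrected` (always `>= p_nominal`).
#' @export
permutation_locus_test <- function(carriers, samples, n_perm = 1000,
                                   seed = NULL,
                                   stratify = c("cohort", "none")) {
  stratify <- match.arg(stratify)
  if (n_perm < 100) abort("n_perm must be at least 100")
  carriers <- as.matrix(carriers) * 1
  if (is.null(colnames(carriers))) {
    colnames(carriers) <- paste0("locus_", seq_len(ncol(carriers)))
  }
  if (ncol(carriers) == 0) abort("no loci to test")
  stopifnot(!is.null(rownames(carriers)))
  idx <- match(samples$sample_id, rownames(carriers))
  if (anyNA(idx)) abort("sample sheet ids missing from carrier matrix")
  carriers <- carriers[idx, , drop = FALSE]

  y <- as.integer(samples$status == "case")
  obs <- drop(crossprod(carriers, y))
  totals <- colSums(carriers)

  strata <- if (stratify == "cohort") {
    if (!"cohort" %in% names(samples)) abort("stratify = 'cohort' needs a cohort column")
    split(seq_along(y), samples$cohort)
  } else {
    list(seq_along(y))
  }

  run <- function() {
    yp <- y
    count_ge <- rep(0L, ncol(carriers))
    count_max_ge <- rep(0L, ncol(carriers))
    for (b in seq_len(n_perm)) {
      for (s in strata) yp[s] <- y[s[sample.int(length(s))]]
      stat <- drop(crossprod(carriers, yp))
      count_ge <- count_ge + (stat >= obs)
      count_max_ge <- count_max_ge + (max(stat) >= obs)
    }
    list(nominal = (1 + count_ge) / (n_perm + 1),
         corrected = (1 + count_max_ge) / (n_perm + 1))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  tibble::tibble(
    locus_id = colnames(carriers),
    case_carriers = as.integer(obs),
    control_carriers = as.integer(totals - obs),
    p_nominal = res$nominal,
    p_corrected = pmax(res$corrected, res$nominal)
  )
}

#' Gene-set burden of rare deletions with platform stratification
#'
#' Tests whether cases are enriched for carrying a rare deletion that
#' intersects a set of genes (e.g. the X-linked cancer-testis antigens).
#' Array platforms differ in probe coverage of any given gene set, so the
#' test statistic (number of case carriers) is assessed by permuting labels
#' *within platform*; platforms with no probe coverage of the set are
#' excluded entirely.
#'
#' @param calls Rare consensus-call tibble (`sample_id`, `chrom`, `start`,
#'   `end`, `cnv_class`).
#' @param samples Sample sheet with `sample_id`, `status`, `platform`.
#' @param gene_set Interval tibble (`chrom`, `start`, `end`) of the set.
#' @param platform_coverage Optional tibble `platform`, `n_probes`;
#'   platforms with `n_probes == 0` are dropped with a message.
#' @param cnv_class Class of events counted (default `"loss"`).
#' @param n_perm,seed Permutation settings as in
#'   [permutation_locus_test()].
#' @return One-row tibble: `case_carriers`, `control_carriers`, `n_case`,
#'   `n_control`, `p_value`.
#' @export
geneset_burden <- function(calls, samples, gene_set, platform_coverage = NULL,
                           cnv_class = "loss", n_perm = 1000, seed = NULL) {
  if (nrow(gene_set) == 0) abort("empty gene set")
  validate_intervals(gene_set, "gene set")
  if (!is.null(platform_coverage)) {
    dead <- platform_coverage$platform[platform_coverage$n_probes == 0]
    if (length(dead) > 0) {
      inform(paste0("excluding platform(s) with no probe coverage of the set: ",
                    paste(dead, collapse = ", ")))
      samples <- dplyr::filter(samples, !.data$platform %in% dead)
    }
  }
  dels <- dplyr::filter(calls, .data$cnv_class == !!cnv_class,
                        .data$sample_id %in% samples$sample_id)
  hit <- function(chrom, start, end) {
    gs <- gene_set[gene_set$chrom == chrom, ]
    nrow(gs) > 0 && any(overlap_bp(start, end, gs$start, gs$end) > 0)
  }
  carrier_ids <- unique(dels$sample_id[
    purrr::pmap_lgl(list(dels$chrom, dels$start, dels$end), hit)
  ])

  carr <- matrix(as.integer(samples$sample_id %in% carrier_ids), ncol = 1,
                 dimnames = list(samples$sample_id, "gene_set"))
  sheet <- dplyr::mutate(samples, cohort = .data$platform)
  res <- permutation_locus_test(carr, sheet, n_perm = n_perm, seed = seed,
                                stratify = "cohort")
  tibble::tibble(
    case_carriers = res$case_carriers,
    control_carriers = res$control_carriers,
    n_case = sum(samples$status == "case"),
    n_control = sum(samples$status == "control"),
    p_value = res$p_nominal
  )
}

#' Compare two sets of deletion scores
#'
#' Summarises and compares score distributions (e.g. haploinsufficiency LOD
#' scores of singleton deletions) between two groups with a two-sided
#' rank-sum test. Cohorts plotted side by side are conventionally ordered
#' by median score; the medians returned here reproduce that layout rule.
#'
#' @param a,b Numeric vectors of scores, or tibbles with a `score` column.
#' @return One-row tibble: `median_a`, `median_b`, `mean_a`, `mean_b`,
#'   `p_value`.
#' @export
compare_score_sets <- function(a, b) {
  if (is.data.frame(a)) a <- a$score
  if (is.data.frame(b)) b <- b$score
  if (length(a) == 0 || length(b) == 0) abort("both score sets must be nonempty")
  p <- ranksum_burden(a, b)$p_value
  tibble::tibble(
    median_a = median(a), median_b = median(b),
    mean_a = mean(a), mean_b = mean(b),
    p_value = p
  )
}
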