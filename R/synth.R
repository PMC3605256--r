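#' Default cohort layout for the synthetic CNV generator
#'
#' Three case-control cohorts, each on its own array platform, sized to
#' the primary CNV analysis of the study design this package supports:
#' 83/62, 179/974 and 61/100 cases/controls (323 cases and 1136 controls
#' in total).
#'
#' @return Tibble `name`, `n_case`, `n_control`, `platform`.
#' @export
default_cohorts <- function() {
  tibble::tribble(
    ~name,       ~n_case, ~n_control, ~platform,
    "cohort1",   83,      62,         "illumina370k",
    "cohort2",   179,     974,        "affy6",
    "cohort3",   61,      100,        "omniexpress"
  )
}

#' Default per-event burden effects
#'
#' Generative per-event log odds ratios by compartment and class:
#' rare autosomal deletions multiply disease odds by 1.10, X-linked CNVs
#' (either class) by 1.29, Y-linked duplications by 1.88; other categories
#' are null.
#'
#' @return Tibble `compartment`, `cnv_class`, `log_or`.
#' @export
default_burden_effect <- function() {
  tibble::tribble(
    ~compartment, ~cnv_class, ~log_or,
    "autosome",   "loss",     log(1.10),
    "autosome",   "gain",     0,
    "X",          "loss",     log(1.29),
    "X",          "gain",     log(1.29),
    "Y",          "loss",     0,
    "Y",          "gain",     log(1.88)
  )
}

#' Default rare-event rates
#'
#' Mean number of true rare events per genome by compartment and class
#' (Poisson). Autosomal rates dominate; sex-chromosome events are rarer,
#' mirroring the relative target sizes.
#'
#' @return Tibble `compartment`, `cnv_class`, `lambda`.
#' @export
default_rare_rates <- function() {
  tibble::tribble(
    ~compartment, ~cnv_class, ~lambda,
    "autosome",   "loss",     2.0,
    "autosome",   "gain",     2.0,
    "X",          "loss",     0.25,
    "X",          "gain",     0.25,
    "Y",          "loss",     0.15,
    "Y",          "gain",     0.15
  )
}

# sample event intervals for one compartment: chromosome by length,
# position uniform, length log-normal (median 30 kb by default)
sample_events <- function(n, compartment, genome, size_meanlog, size_sdlog) {
  chroms <- genome[compartment_of(genome$chrom, genome) == compartment, ]
  ci <- sample.int(nrow(chroms), n, replace = TRUE, prob = chroms$length)
  len <- pmax(500, round(rlnorm(n, size_meanlog, size_sdlog)))
  clen <- chroms$length[ci]
  len <- pmin(len, floor(clen * 0.5))
  start <- floor(runif(n, 0, clen - len))
  tibble::tibble(chrom = chroms$chrom[ci], start = start, end = start + len)
}

#' Simulate a multi-cohort case-control CNV study with known ground truth
#'
#' Emulates the data structure of an array-based rare-CNV case-control
#' study: per-sample true events (rare events Poisson per compartment and
#' class, plus shared common polymorphic regions), case status drawn from
#' a logistic model on the rare-event counts with the supplied per-event
#' log odds ratios, and a noisy multi-algorithm calling channel in which
#' each true event is observed per algorithm with a given sensitivity and
#' Gaussian breakpoint jitter -- so 2-of-3 consensus recovery, clustering,
#' frequency filtering and burden estimation are all exercised end to end.
#'
#' Case/control quotas per cohort are filled by retrospective sampling
#' (candidates are generated and sampled until each quota is met), which
#' leaves the burden log odds ratio identifiable while fixing the design
#' margins.
#'
#' @param cohorts Cohort layout, see [default_cohorts()].
#' @param genome Genome manifest.
#' @param rare_rates Per-category Poisson rates, see [default_rare_rates()].
#' @param burden_effect Per-category log odds ratios, see
#'   [default_burden_effect()].
#' @param common_region_count Number of shared common polymorphic regions.
#' @param common_freq_range Carrier-frequency range for common regions.
#' @param size_meanlog,size_sdlog Log-normal event size parameters
#'   (default median 30 kb, sigma 1.2 on the log scale).
#' @param algorithms Calling algorithm labels.
#' @param sensitivity Per-algorithm detection probability.
#' @param jitter_sd Breakpoint jitter standard deviation in bp.
#' @param n_covariates Number of ancestry covariates (cohort-shifted
#'   standard normals).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return List with `calls` (per-algorithm call tibble), `samples`
#'   (sample sheet) and `truth` (true events, per-sample rare counts,
#'   generative effects).
#' @export
simulate_cnv_cohort <- function(cohorts = default_cohorts(),
                                genome = toy_genome(),
                                rare_rates = default_rare_rates(),
                                burden_effect = default_burden_effect(),
                                common_region_count = 20,
                                common_freq_range = c(0.05, 0.4),
                                size_meanlog = log(3e4), size_sdlog = 1.2,
                                algorithms = c("gada", "penncnv", "quantisnp"),
                                sensitivity = c(0.95, 0.90, 0.85),
                                jitter_sd = 2000,
                                n_covariates = 10, seed = NULL) {
  stopifnot(length(sensitivity) == length(algorithms))
  if (any(cohorts$n_case + cohorts$n_control <= 0)) abort("empty cohort")
  if (any(rare_rates$lambda < 0)) abort("negative rare rate")
  run <- function() {
    sim_cnv_impl(cohorts, genome, rare_rates, burden_effect,
                 common_region_count, common_freq_range,
                 size_meanlog, size_sdlog, algorithms, sensitivity,
                 jitter_sd, n_covariates)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

sim_cnv_impl <- function(cohorts, genome, rare_rates, burden_effect,
                         common_region_count, common_freq_range,
                         size_meanlog, size_sdlog, algorithms, sensitivity,
                         jitter_sd, n_covariates) {
  cat_key <- paste(rare_rates$compartment, rare_rates$cnv_class, sep = "_")
  beta <- burden_effect$log_or[match(
    cat_key, paste(burden_effect$compartment, burden_effect$cnv_class, sep = "_")
  )]
  beta[is.na(beta)] <- 0
  alpha <- -sum(beta * rare_rates$lambda)  # center P(case) near 0.5

  # shared common polymorphic regions (status-independent)
  common <- dplyr::bind_rows(
    sample_events(max(1, round(common_region_count * 0.8)), "autosome",
                  genome, size_meanlog, size_sdlog),
    sample_events(max(1, common_region_count -
                        round(common_region_count * 0.8)), "X",
                  genome, size_meanlog, size_sdlog)
  ) |>
    head(common_region_count) |>
    dplyr::mutate(
      cnv_class = sample(c("gain", "loss"), dplyr::n(), replace = TRUE),
      freq = runif(dplyr::n(), common_freq_range[1], common_freq_range[2]),
      common_id = sprintf("common_%03d", seq_len(dplyr::n()))
    )

  sheets <- list(); truths <- list(); all_calls <- list()
  cov_shift <- matrix(rnorm(nrow(cohorts) * n_covariates, 0, 0.5),
                      nrow = nrow(cohorts))

  for (ci in seq_len(nrow(cohorts))) {
    quota_case <- cohorts$n_case[ci]
    quota_ctrl <- cohorts$n_control[ci]
    got_case <- 0; got_ctrl <- 0
    keep_counts <- list(); keep_status <- character()
    tries <- 0
    while ((got_case < quota_case || got_ctrl < quota_ctrl) && tries < 60) {
      tries <- tries + 1
      m <- 2 * (quota_case + quota_ctrl - got_case - got_ctrl) + 50
      counts <- matrix(
        rpois(m * nrow(rare_rates), rep(rare_rates$lambda, each = m)),
        nrow = m
      )
      lp <- alpha + drop(counts %*% beta)
      status <- ifelse(runif(m) < plogis(lp), "case", "control")
      take <- (status == "case" & cumsum(status == "case") + got_case <= quota_case) |
        (status == "control" & cumsum(status == "control") + got_ctrl <= quota_ctrl)
      keep_counts[[tries]] <- counts[take, , drop = FALSE]
      keep_status <- c(keep_status, status[take])
      got_case <- sum(keep_status == "case")
      got_ctrl <- sum(keep_status == "control")
    }
    if (got_case < quota_case || got_ctrl < quota_ctrl) {
      abort("infeasible simulation config: could not fill case/control quota")
    }
    counts <- do.call(rbind, keep_counts)
    n <- nrow(counts)
    ids <- sprintf("%s_s%04d", cohorts$name[ci], seq_len(n))

    covs <- matrix(rnorm(n * n_covariates), nrow = n) +
      matrix(cov_shift[ci, ], nrow = n, ncol = n_covariates, byrow = TRUE)
    colnames(covs) <- paste0("cov", seq_len(n_covariates))
    sheets[[ci]] <- dplyr::bind_cols(
      tibble::tibble(sample_id = ids, status = keep_status,
                     cohort = cohorts$name[ci],
                     platform = cohorts$platform[ci]),
      tibble::as_tibble(covs)
    )

    # materialise rare events for the selected samples
    ev <- list()
    for (k in seq_len(nrow(rare_rates))) {
      nk <- counts[, k]
      tot <- sum(nk)
      if (tot == 0) next
      e <- sample_events(tot, rare_rates$compartment[k], genome,
                         size_meanlog, size_sdlog)
      e$sample_id <- rep(ids, nk)
      e$cnv_class <- rare_rates$cnv_class[k]
      e$compartment <- rare_rates$compartment[k]
      ev[[k]] <- e
    }
    rare_events <- dplyr::bind_rows(ev)

    # common-region carriage
    carr <- lapply(seq_len(nrow(common)), function(r) {
      who <- ids[runif(n) < common$freq[r]]
      if (length(who) == 0) return(NULL)
      tibble::tibble(sample_id = who, chrom = common$chrom[r],
                     start = common$start[r], end = common$end[r],
                     cnv_class = common$cnv_class[r],
                     compartment = compartment_of(common$chrom[r], genome),
                     common_id = common$common_id[r])
    })
    common_events <- dplyr::bind_rows(carr)

    truth_events <- dplyr::bind_rows(
      dplyr::mutate(rare_events, origin = "rare"),
      dplyr::mutate(common_events, origin = "common")
    )
    truth_counts <- tibble::as_tibble(counts, .name_repair = ~cat_key) |>
      dplyr::mutate(sample_id = ids, .before = 1)

    # noisy multi-algorithm emission channel
    calls <- list()
    clen <- stats::setNames(genome$length, genome$chrom)
    for (j in seq_along(algorithms)) {
      det <- runif(nrow(truth_events)) < sensitivity[j]
      e <- truth_events[det, ]
      if (nrow(e) == 0) next
      s <- round(e$start + rnorm(nrow(e), 0, jitter_sd))
      en <- round(e$end + rnorm(nrow(e), 0, jitter_sd))
      s <- pmax(0, s)
      en <- pmin(unname(clen[e$chrom]), en)
      bad <- en <= s
      if (any(bad)) {  # jitter collapsed the event: keep a minimal interval
        mid <- floor((e$start[bad] + e$end[bad]) / 2)
        s[bad] <- mid; en[bad] <- mid + 1
      }
      calls[[j]] <- tibble::tibble(
        sample_id = e$sample_id, chrom = e$chrom, start = s, end = en,
        cnv_class = e$cnv_class, algorithm = algorithms[j],
        platform = cohorts$platform[ci]
      )
    }
    cohort_calls <- dplyr::bind_rows(calls)
    # drop exact duplicate emissions (distinct true events can collapse to
    # the same rounded interval under jitter)
    cohort_calls <- dplyr::distinct(
      cohort_calls, .data$sample_id, .data$algorithm, .data$chrom,
      .data$start, .data$end, .data$cnv_class, .keep_all = TRUE
    )
    all_calls[[ci]] <- cohort_calls
    truths[[ci]] <- list(events = truth_events, counts = truth_counts)
  }

  samples <- dplyr::bind_rows(sheets)
  list(
    calls = dplyr::bind_rows(all_calls),
    samples = samples,
    truth = list(
      events = dplyr::bind_rows(lapply(truths, `[[`, "events")),
      counts = dplyr::bind_rows(lapply(truths, `[[`, "counts")),
      burden_effect = burden_effect,
      common_regions = common,
      alpha = alpha
    )
  )
}

#' Simulate homozygosity-by-descent segments
#'
#' Generates per-sample HBD tracts under a simple identity-by-descent
#' model: for a sample whose parents share an ancestor `generations` back,
#' autozygous segment lengths are exponential with mean `100 / (2 *
#' generations)` centimorgans (16.7 cM for first-cousin offspring), mapped
#' to base pairs at a uniform `cM_per_Mb`. Segment starts follow a
#' stationary Poisson (Boolean) process whose intensity is chosen so the
#' expected covered fraction of the autosomes equals the sample's target
#' inbreeding coefficient `f_target` (1/16 for first-cousin offspring). A
#' low-coverage short-segment background is added to every sample, and
#' whole-chromosome segments can be injected to emulate uniparental
#' isodisomy.
#'
#' @param samples Tibble with `sample_id` and optionally a per-sample
#'   `f_target` column (default 0 = outbred).
#' @param genome Genome manifest; segments are generated on autosomes.
#' @param f_target Scalar fallback target F for samples without their own.
#' @param generations Generations to the shared ancestor (3 = first
#'   cousins).
#' @param background_coverage Expected genome fraction in short background
#'   homozygosity tracts.
#' @param background_mean_len Mean background tract length in bp.
#' @param cM_per_Mb Recombination map density.
#' @param upd Optional tibble `sample_id`, `chrom`: inject a
#'   whole-chromosome segment for each row.
#' @param seed Optional integer seed.
#' @return List with `segments` (`sample_id`, `chrom`, `start`, `end`) and
#'   `truth` (per-sample `f_target`, plus the `upd` table).
#' @export
simulate_hbd <- function(samples, genome = toy_genome(), f_target = 0,
                         generations = 3,
                         background_coverage = 0.001,
                         background_mean_len = 5e5,
                         cM_per_Mb = 1, upd = NULL, seed = NULL) {
  run <- function() {
    validate_genome(genome)
    autosomes <- genome[compartment_of(genome$chrom, genome) == "autosome", ]
    ft <- if ("f_target" %in% names(samples)) samples$f_target else
      rep(f_target, nrow(samples))
    mean_len <- (100 / (2 * generations)) / cM_per_Mb * 1e6  # bp

    boolean_segments <- function(coverage, mean_len_bp) {
      if (coverage <= 0) return(NULL)
      rho <- -log(1 - coverage) / mean_len_bp
      segs <- lapply(seq_len(nrow(autosomes)), function(a) {
        L <- autosomes$length[a]
        B <- 8 * mean_len_bp
        n <- rpois(1, rho * (L + B))
        if (n == 0) return(NULL)
        s <- runif(n, -B, L)
        e <- s + rexp(n, 1 / mean_len_bp)
        s <- pmax(0, s); e <- pmin(L, e)
        keep <- e - s >= 1
        if (!any(keep)) return(NULL)
        tibble::tibble(chrom = autosomes$chrom[a],
                       start = floor(s[keep]), end = ceiling(e[keep]))
      })
      dplyr::bind_rows(segs)
    }

    out <- lapply(seq_len(nrow(samples)), function(i) {
      segs <- dplyr::bind_rows(
        boolean_segments(ft[i], mean_len),
        boolean_segments(background_coverage, background_mean_len)
      )
      if (nrow(segs) == 0) return(NULL)
      dplyr::mutate(segs, sample_id = samples$sample_id[i], .before = 1)
    })
    segments <- dplyr::bind_rows(out)

    if (!is.null(upd) && nrow(upd) > 0) {
      inj <- upd |>
        dplyr::inner_join(genome, by = "chrom") |>
        dplyr::transmute(.data$sample_id, .data$chrom,
                         start = 0, end = .data$length)
      segments <- dplyr::bind_rows(segments, inj)
    }
    list(
      segments = dplyr::arrange(segments, .data$sample_id, .data$chrom,
                                .data$start),
      truth = list(f = tibble::tibble(sample_id = samples$sample_id,
                                      f_target = ft),
                   upd = upd)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a subject exome and reference panel for variant prioritisation
#'
#' Draws annotator scores from benign-skewed beta distributions on the
#' normalized scale (mapped back to each annotator's raw range, with the
#' SIFT direction flipped), assigns mostly heterozygous genotypes and
#' uniform reference-panel allele frequencies, and plants one homozygous
#' variant with maximally damaging scores in a gene absent from the panel
#' and below the MAF filter -- the structural analogue of a single extreme
#' recessive hit discoverable by the two-dimensional score.
#'
#' @param n_genes Gene universe size (one gene is reserved, panel-absent,
#'   for the planted hit).
#' @param n_subject,n_panel Numbers of subject and panel variants.
#' @param hom_fraction Fraction of homozygous genotypes.
#' @param benign_shape Beta shape parameters of the normalized score
#'   distribution (benign-skewed by default).
#' @param spec Normalization spec used to map normalized draws to raw
#'   scores.
#' @param planted Logical: plant the extreme homozygous variant?
#' @param seed Optional integer seed.
#' @return List with `subject`, `panel` (variant tibbles) and `truth`
#'   (`planted_id`, `planted_gene`).
#' @export
simulate_exome <- function(n_genes = 500, n_subject = 800, n_panel = 2000,
                           hom_fraction = 0.05, benign_shape = c(0.8, 4),
                           spec = default_normalization(), planted = TRUE,
                           seed = NULL) {
  run <- function() {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    reserved <- genes[1]
    draw <- function(n, gene_pool, prefix) {
      norm <- matrix(rbeta(n * nrow(spec), benign_shape[1], benign_shape[2]),
                     nrow = n)
      raw <- sapply(seq_len(nrow(spec)), function(i) {
        v <- norm[, i]
        if (spec$direction[i] == "descending") v <- 1 - v
        spec$min[i] + v * (spec$max[i] - spec$min[i])
      })
      colnames(raw) <- spec$annotator
      tibble::tibble(
        variant_id = sprintf("%s_%05d", prefix, seq_len(n)),
        gene = sample(gene_pool, n, replace = TRUE),
        ploidy = 1 + rbinom(n, 1, hom_fraction)
      ) |>
        dplyr::bind_cols(tibble::as_tibble(raw)) |>
        dplyr::mutate(maf_panel_1 = runif(n, 0, 0.3),
                      maf_panel_2 = runif(n, 0, 0.3))
    }
    subject <- draw(n_subject, genes[-1], "var_s")
    panel <- draw(n_panel, genes[-1], "var_p")
    truth <- list(planted_id = NA_character_, planted_gene = NA_character_)
    if (planted) {
      hit <- subject[1, ]
      hit$variant_id <- "var_planted"
      hit$gene <- reserved
      hit$ploidy <- 2
      for (i in seq_len(nrow(spec))) {
        hit[[spec$annotator[i]]] <-
          if (spec$direction[i] == "descending") spec$min[i] else spec$max[i]
      }
      hit$maf_panel_1 <- 0.01
      hit$maf_panel_2 <- 0.01
      subject <- dplyr::bind_rows(subject, hit)
      truth <- list(planted_id = "var_planted", planted_gene = reserved)
    }
    list(subject = subject, panel = panel, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
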