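variant_row <- function(variant_id = "v1", gene = "g1", ploidy = 1,
                        phylop = 0, polyphen2 = 0, sift = 1, gerp = 0,
                        lrt = 0, maf_panel_1 = 0.01, maf_panel_2 = 0.01) {
  tibble::tibble(variant_id = variant_id, gene = gene, ploidy = ploidy,
                 phylop = phylop, polyphen2 = polyphen2, sift = sift,
                 gerp = gerp, lrt = lrt,
                 maf_panel_1 = maf_panel_1, maf_panel_2 = maf_panel_2)
}

damaging_extreme <- function(...) {
  variant_row(phylop = 6, polyphen2 = 1, sift = 0, gerp = 6.17, lrt = 1, ...)
}

benign_extreme <- function(...) {
  variant_row(phylop = -14, polyphen2 = 0, sift = 1, gerp = -12.3, lrt = 0, ...)
}

norm_cols <- paste0("norm_", default_normalization()$annotator)

test_that("normalization maps extremes to 0/1 and midpoints to 0.5, flipping SIFT", {
  expect_equal(unlist(normalize_scores(damaging_extreme())[, norm_cols]),
               setNames(rep(1, 5), norm_cols))
  expect_equal(unlist(normalize_scores(benign_extreme())[, norm_cols]),
               setNames(rep(0, 5), norm_cols))
  mid <- variant_row(phylop = -4, polyphen2 = 0.5, sift = 0.5,
                     gerp = (6.17 - 12.3) / 2, lrt = 0.5)
  expect_equal(unlist(normalize_scores(mid)[, norm_cols]),
               setNames(rep(0.5, 5), norm_cols))
})

test_that("out-of-range raw scores are clamped with a message", {
  v <- variant_row(phylop = 99, gerp = -99)
  expect_message(out <- normalize_scores(v), "clamped")
  expect_equal(out$norm_phylop, 1)
  expect_equal(out$norm_gerp, 0)
})

test_that("missing annotator values normalize to benign or drop the variant", {
  v <- variant_row(phylop = NA)
  expect_equal(normalize_scores(v)$norm_phylop, 0)
  expect_message(out <- normalize_scores(v, na_action = "drop"), "dropped 1")
  expect_equal(nrow(out), 0)
})

test_that("individual score is the ploidy-weighted sum, bounded by 10", {
  hom <- individual_score(normalize_scores(damaging_extreme(ploidy = 2)))
  expect_equal(hom$p_ind, 10)
  het <- individual_score(normalize_scores(damaging_extreme(ploidy = 1)))
  expect_equal(het$p_ind, 5)
  expect_equal(hom$p_ind, 2 * het$p_ind)
  expect_error(
    individual_score(normalize_scores(variant_row(ploidy = 3))),
    "ploidy"
  )
})

test_that("gene maxima match a brute-force scan; absent genes map to 0", {
  withr::with_seed(91, {
    panel <- dplyr::bind_rows(lapply(1:300, function(i) {
      variant_row(variant_id = paste0("p", i),
                  gene = sample(paste0("g", 1:40), 1),
                  ploidy = sample(1:2, 1),
                  phylop = runif(1, -14, 6), polyphen2 = runif(1),
                  sift = runif(1), gerp = runif(1, -12.3, 6.17),
                  lrt = runif(1))
    }))
    gm <- build_gene_max(panel)
    scored <- individual_score(normalize_scores(panel))
    brute <- tapply(scored$p_ind, scored$gene, max)
    expect_equal(gm$p_max, as.numeric(brute[gm$gene]))
    # a gene absent from the panel contributes p_max 0
    novel <- population_score(
      individual_score(normalize_scores(damaging_extreme(gene = "not_in_panel",
                                                         ploidy = 2))), gm)
    expect_equal(novel$p_max, 0)
    expect_equal(novel$p_pop, 10)
  })
})

test_that("a panel variant that is its gene's maximum has population score 0", {
  panel <- damaging_extreme(variant_id = "p1", gene = "gA", ploidy = 2)
  gm <- build_gene_max(panel)
  self <- population_score(individual_score(normalize_scores(panel)), gm)
  expect_equal(self$p_pop, 0)
  weaker <- population_score(
    individual_score(normalize_scores(variant_row(gene = "gA", polyphen2 = 0.5))),
    gm)
  expect_lt(weaker$p_pop, 0)
})

test_that("MAF filter requires both panels strictly under the cutoff", {
  v <- dplyr::bind_rows(
    variant_row("keep", maf_panel_1 = 0.09, maf_panel_2 = 0.09),
    variant_row("drop_one", maf_panel_1 = 0.09, maf_panel_2 = 0.12),
    variant_row("drop_edge", maf_panel_1 = 0.10, maf_panel_2 = 0.05)
  )
  expect_identical(maf_filter(v)$variant_id, "keep")
  v$maf_panel_2[1] <- NA
  expect_message(out <- maf_filter(v), "treated as 0")
  expect_identical(out$variant_id, "keep")
})

test_that("ranking orders by p_pop, then p_ind, then id, independent of input order", {
  sc <- tibble::tibble(
    variant_id = c("b", "a", "c", "d"),
    p_pop = c(2, 2, 5, 2), p_ind = c(4, 4, 6, 9)
  )
  r <- rank_variants(sc)
  expect_identical(r$variant_id, c("c", "d", "a", "b"))
  r_rev <- rank_variants(sc[4:1, ])
  expect_identical(r_rev$variant_id, r$variant_id)
})

test_that("score bounds and monotonicity hold under random fuzzing", {
  withr::with_seed(92, {
    spec <- default_normalization()
    for (i in 1:100) {
      v <- variant_row(ploidy = sample(1:2, 1),
                       phylop = runif(1, -30, 30), polyphen2 = runif(1, -1, 2),
                       sift = runif(1, -1, 2), gerp = runif(1, -30, 30),
                       lrt = runif(1, -1, 2))
      s <- suppressMessages(individual_score(normalize_scores(v)))
      expect_gte(s$p_ind, 0); expect_lte(s$p_ind, 10)
      # increasing one normalized component never decreases the score
      bumped <- v
      bumped$polyphen2 <- min(1, max(0, v$polyphen2) + 0.1)
      s2 <- suppressMessages(individual_score(normalize_scores(bumped)))
      expect_gte(s2$p_ind + 1e-12, s$p_ind)
    }
  })
})

test_that("end-to-end scoring ranks the planted extreme homozygote first", {
  ex <- simulate_exome(n_subject = 300, n_panel = 800, seed = 93)
  sc <- score_variants(ex$subject, ex$panel)
  expect_identical(sc$variant_id[1], ex$truth$planted_id)
  expect_equal(sc$p_ind[1], 10)
  expect_equal(sc$p_pop[1], 10)
  # unique maximum on both scales
  expect_lt(max(sc$p_pop[-1]), sc$p_pop[1])
  expect_true(all(sc$p_pop <= sc$p_ind + 1e-12))
})
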