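small_cohorts <- tibble::tibble(
  name = c("ca", "cb"), n_case = c(15, 10), n_control = c(20, 25),
  platform = c("pA", "pB")
)

test_that("fixed seeds give identical simulated datasets", {
  a <- simulate_cnv_cohort(small_cohorts, seed = 101)
  b <- simulate_cnv_cohort(small_cohorts, seed = 101)
  expect_identical(a, b)
  c_ <- simulate_cnv_cohort(small_cohorts, seed = 102)
  expect_false(identical(a$calls, c_$calls))

  h1 <- simulate_hbd(tibble::tibble(sample_id = "s1", f_target = 0.0625),
                     seed = 5)
  h2 <- simulate_hbd(tibble::tibble(sample_id = "s1", f_target = 0.0625),
                     seed = 5)
  expect_identical(h1, h2)

  e1 <- simulate_exome(n_subject = 50, n_panel = 100, seed = 7)
  e2 <- simulate_exome(n_subject = 50, n_panel = 100, seed = 7)
  expect_identical(e1, e2)
})

test_that("cohort quotas are filled exactly with the requested platforms", {
  sim <- simulate_cnv_cohort(small_cohorts, seed = 103)
  tab <- table(sim$samples$cohort, sim$samples$status)
  expect_equal(unname(tab["ca", "case"]), 15)
  expect_equal(unname(tab["ca", "control"]), 20)
  expect_equal(unname(tab["cb", "case"]), 10)
  expect_equal(unname(tab["cb", "control"]), 25)
  expect_true(all(sim$samples$platform[sim$samples$cohort == "ca"] == "pA"))
  expect_equal(sum(grepl("^cov", names(sim$samples))), 10)
})

test_that("a lossless channel lets consensus reconstruct the true events", {
  sim <- simulate_cnv_cohort(small_cohorts, sensitivity = c(1, 1, 1),
                             jitter_sd = 0, common_region_count = 1,
                             seed = 104)
  cons <- consensus_merge(sim$calls[sim$calls$platform == "pA", ])
  truth <- sim$truth$events[
    sim$truth$events$sample_id %in%
      sim$samples$sample_id[sim$samples$platform == "pA"], ]
  # every true event is recovered with full support at exact coordinates
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$start, d$end, d$cnv_class))
  expect_identical(key(cons), key(unique(truth[, c("sample_id", "chrom",
                                                   "start", "end", "cnv_class")])))
  expect_true(all(cons$n_algorithms == 3))
})

test_that("a dead third algorithm still yields two supports everywhere", {
  sim <- simulate_cnv_cohort(small_cohorts, sensitivity = c(1, 1, 0),
                             jitter_sd = 0, common_region_count = 1,
                             seed = 105)
  cons <- consensus_merge(sim$calls[sim$calls$platform == "pA", ])
  expect_true(all(cons$n_algorithms == 2))
  expect_gt(nrow(cons), 0)
})

test_that("null burden effects leave case and control counts exchangeable", {
  withr::with_seed(106, {
    null_effect <- dplyr::mutate(default_burden_effect(), log_or = 0)
    ps <- replicate(40, {
      sim <- simulate_cnv_cohort(
        tibble::tibble(name = "c1", n_case = 40, n_control = 40,
                       platform = "p"),
        burden_effect = null_effect, common_region_count = 1
      )
      counts <- sim$truth$counts
      tot <- rowSums(counts[, -1])
      st <- sim$samples$status[match(counts$sample_id, sim$samples$sample_id)]
      ranksum_burden(tot[st == "case"], tot[st == "control"])$p_value
    })
    # p roughly uniform: no mass collapse at small values
    expect_gt(mean(ps > 0.05), 0.8)
    expect_gt(min(ps), 0.001)
  })
})

test_that("infeasible configurations are rejected", {
  expect_error(
    simulate_cnv_cohort(tibble::tibble(name = "x", n_case = 0, n_control = 0,
                                       platform = "p"), seed = 1),
    "empty cohort"
  )
  expect_error(
    simulate_cnv_cohort(small_cohorts,
                        rare_rates = dplyr::mutate(default_rare_rates(),
                                                   lambda = -1)),
    "negative"
  )
})

test_that("background-only HBD stays below the first classification threshold", {
  sim <- simulate_hbd(tibble::tibble(sample_id = sprintf("s%03d", 1:100)),
                      f_target = 0, seed = 107)
  prof <- inbreeding_coefficient(
    sim$segments,
    samples = tibble::tibble(sample_id = sprintf("s%03d", 1:100))
  )
  expect_gte(mean(prof$f_hat < 0.005), 0.95)
})

test_that("injected UPD is exactly the flagged sample-chromosome pair", {
  upd <- tibble::tibble(sample_id = "s002", chrom = "chr2")
  sim <- simulate_hbd(tibble::tibble(sample_id = sprintf("s%03d", 1:5)),
                      f_target = 0, upd = upd, seed = 108)
  flags <- detect_upd(sim$segments)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$sample_id, "s002")
  expect_equal(flags$chrom, "chr2")
})

test_that("generated tables round-trip losslessly through the TSV writers", {
  withr::with_seed(109, {
    sim <- simulate_cnv_cohort(small_cohorts, seed = 110)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_tsv_table(sim$calls, tmp)
    back <- read_cnv_calls(tmp)
    expect_equal(as.data.frame(back), as.data.frame(sim$calls))

    hb <- simulate_hbd(tibble::tibble(sample_id = "s1", f_target = 0.3),
                       seed = 111)
    tmp2 <- withr::local_tempfile(fileext = ".tsv")
    write_tsv_table(hb$segments, tmp2)
    expect_equal(as.data.frame(read_hbd_segments(tmp2)),
                 as.data.frame(hb$segments))
  })
})
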