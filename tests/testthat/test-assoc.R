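test_that("carrier tables partition the sample sheet by status and carriage", {
  sheet <- make_sheet(323, 1124)
  carriers <- c(sheet$sample_id[1:9], sheet$sample_id[324:331])
  tab <- carrier_table(carriers, sheet)
  expect_equal(unlist(tab), c(case_carriers = 9, case_noncarriers = 314,
                              control_carriers = 8, control_noncarriers = 1116))
  none <- carrier_table(character(), sheet)
  expect_equal(none$case_carriers + none$case_noncarriers, 323)
  expect_equal(none$control_carriers, 0)
  expect_error(carrier_table("ghost", sheet), "absent")
})

test_that("combine_counts is a cellwise sum", {
  t1 <- tibble::tibble(case_carriers = 9, case_noncarriers = 314,
                       control_carriers = 8, control_noncarriers = 1116)
  t2 <- tibble::tibble(case_carriers = 3, case_noncarriers = 400,
                       control_carriers = 10, control_noncarriers = 2111)
  comb <- combine_counts(list(t1, t2))
  expect_equal(unlist(comb), c(case_carriers = 12, case_noncarriers = 714,
                               control_carriers = 18, control_noncarriers = 3227))
  expect_equal(combine_counts(list(t1)), t1)
})

test_that("fisher_exact matches the fixed-margins enumeration oracle", {
  withr::with_seed(41, {
    for (i in 1:150) {
      x <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
      if (sum(x) == 0) next
      got <- fisher_exact(x)
      want <- oracle_fisher(x[1], x[2], x[3], x[4])
      expect_equal(got$p_two_sided, want$p_two, tolerance = 1e-12)
      expect_equal(got$p_one_sided, want$p_one, tolerance = 1e-12)
    }
  })
})

test_that("exact p agrees with stats::fisher.test as an independent cross-check", {
  tables <- list(c(9, 314, 8, 1116), c(12, 714, 18, 3227),
                 c(5, 1301, 0, 2858), c(8, 171, 13, 959), c(5, 5, 3, 7))
  for (x in tables) {
    m <- matrix(x, 2, byrow = TRUE)
    expect_equal(fisher_exact(x)$p_two_sided, fisher.test(m)$p.value,
                 tolerance = 1e-8)
    expect_equal(fisher_exact(x)$p_one_sided,
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("p is invariant under simultaneous swap of rows and columns", {
  withr::with_seed(42, {
    for (i in 1:50) {
      x <- as.integer(rmultinom(1, sample(6:40, 1), rep(0.25, 4)))
      swapped <- x[c(4, 3, 2, 1)]
      expect_equal(fisher_exact(x)$p_two_sided,
                   fisher_exact(swapped)$p_two_sided, tolerance = 1e-12)
    }
  })
})

test_that("no carriers anywhere gives p = 1 and all-zero tables error", {
  expect_equal(fisher_exact(c(0, 10, 0, 10))$p_two_sided, 1)
  expect_error(fisher_exact(c(0, 0, 0, 0)), "all-zero")
})

test_that("sample odds ratio is the cross-product ratio; symmetric tables give 1", {
  expect_equal(odds_ratio(c(8, 171, 13, 959), method = "sample")$odds_ratio,
               8 * 959 / (171 * 13))
  expect_equal(odds_ratio(c(12, 714, 18, 3227), method = "sample")$odds_ratio,
               12 * 3227 / (714 * 18))
  expect_equal(odds_ratio(c(5, 20, 5, 20), method = "sample")$odds_ratio, 1)
})

test_that("conditional MLE matches fisher.test's conditional estimate and CI", {
  tables <- list(c(9, 314, 8, 1116), c(12, 714, 18, 3227),
                 c(8, 171, 13, 959), c(5, 5, 3, 7))
  for (x in tables) {
    got <- odds_ratio(x, method = "conditional_mle",
                      ci_method = "exact_conditional")
    ref <- fisher.test(matrix(x, 2, byrow = TRUE))
    expect_equal(got$odds_ratio, unname(ref$estimate), tolerance = 1e-3)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-3)
  }
})

test_that("zero-cell policies behave as declared", {
  x <- c(5, 1301, 0, 2858)
  inf <- odds_ratio(x, zero_policy = "infinite")
  expect_identical(inf$odds_ratio, Inf)
  expect_equal(inf$ci_low, 2.009, tolerance = 1e-3)  # cross-checked vs fisher.test
  expect_identical(inf$ci_high, Inf)
  hald <- odds_ratio(x, method = "sample", ci_method = "woolf",
                     zero_policy = "haldane")
  expect_equal(hald$odds_ratio, (5.5 * 2858.5) / (1301.5 * 0.5))
  expect_error(odds_ratio(x, method = "sample", zero_policy = "strict"),
               "undefined")
})

test_that("CMLE sits between the Haldane-corrected and sample OR and converges", {
  withr::with_seed(43, {
    for (i in 1:30) {
      x <- sample(1:15, 4, replace = TRUE)
      or_s <- (x[1] * x[4]) / (x[2] * x[3])
      if (abs(log(or_s)) < 1e-8) next
      or_h <- ((x[1] + .5) * (x[4] + .5)) / ((x[2] + .5) * (x[3] + .5))
      or_c <- odds_ratio(x, method = "conditional_mle")$odds_ratio
      expect_gte(or_c, min(or_s, or_h) - 1e-6)
      expect_lte(or_c, max(or_s, or_h) + 1e-6)
    }
    # convergence to the sample OR as cells grow
    base <- c(8, 171, 13, 959)
    or_s <- (base[1] * base[4]) / (base[2] * base[3])
    d10 <- abs(odds_ratio(base * 10)$odds_ratio - or_s)
    d100 <- abs(odds_ratio(base * 100)$odds_ratio - or_s)
    d1 <- abs(odds_ratio(base)$odds_ratio - or_s)
    expect_lt(d10, d1)
    expect_lt(d100, d10)
  })
})

test_that("Woolf CI contains the sample OR; exact CI contains the CMLE", {
  withr::with_seed(44, {
    for (i in 1:30) {
      x <- sample(1:20, 4, replace = TRUE)
      w <- odds_ratio(x, method = "sample", ci_method = "woolf")
      expect_gte(w$odds_ratio, w$ci_low)
      expect_lte(w$odds_ratio, w$ci_high)
      e <- odds_ratio(x, method = "conditional_mle",
                      ci_method = "exact_conditional")
      expect_gte(e$odds_ratio, e$ci_low)
      expect_lte(e$odds_ratio, e$ci_high)
    }
  })
})

test_that("tidy() exposes the estimate, interval and p-value", {
  td <- tidy(odds_ratio(c(8, 171, 13, 959)))
  expect_named(td, c("term", "estimate", "conf.low", "conf.high", "p.value"))
  expect_equal(td$p.value, fisher_exact(c(8, 171, 13, 959))$p_two_sided)
})
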