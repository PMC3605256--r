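#' Build a 2x2 carrier table
#'
#' Partitions a sample sheet by case/control status and carriage of a locus,
#' yielding the 2x2 table on which exact association tests operate.
#'
#' @param carriers Character vector of carrier sample ids, or a one-row
#'   region tibble from [cluster_cnvrs()] (its `carrier_samples` column is
#'   used).
#' @param samples Sample sheet with `sample_id` and `status`
#'   (`"case"`/`"control"`).
#' @return One-row tibble with `case_carriers`, `case_noncarriers`,
#'   `control_carriers`, `control_noncarriers`.
#' @export
#' @examples
#' sheet <- tibble::tibble(
#'   sample_id = paste0("s", 1:6),
#'   status = rep(c("case", "control"), each = 3)
#' )
#' carrier_table(c("s1", "s5"), sheet)
carrier_table <- function(carriers, samples) {
  if (is.data.frame(carriers)) {
    stopifnot("carrier_samples" %in% names(carriers), nrow(carriers) == 1)
    carriers <- carriers$carrier_samples[[1]]
  }
  missing_ids <- setdiff(carriers, samples$sample_id)
  if (length(missing_ids) > 0) {
    abort(paste0("carrier id(s) absent from sample sheet: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  is_case <- samples$status == "case"
  is_carrier <- samples$sample_id %in% carriers
  tibble::tibble(
    case_carriers = sum(is_case & is_carrier),
    case_noncarriers = sum(is_case & !is_carrier),
    control_carriers = sum(!is_case & is_carrier),
    control_noncarriers = sum(!is_case & !is_carrier)
  )
}

#' Cellwise sum of carrier tables
#'
#' Pools evidence across studies or assay batches by adding the
#' corresponding cells of several 2x2 carrier tables.
#'
#' @param tables A tibble of carrier tables (one per row) or a list of
#'   one-row tables.
#' @return One-row carrier-table tibble.
#' @export
combine_counts <- function(tables) {
  if (!is.data.frame(tables)) tables <- dplyr::bind_rows(tables)
  if (nrow(tables) == 0) abort("no tables to combine")
  dplyr::summarise(tables, dplyr::across(
    c("case_carriers", "case_noncarriers",
      "control_carriers", "control_noncarriers"), sum
  ))
}

# normalize a carrier-table argument to a named numeric c(a, b, c, d)
as_counts <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(nrow(table) == 1)
    x <- c(table$case_carriers, table$case_noncarriers,
           table$control_carriers, table$control_noncarriers)
  } else {
    stopifnot(length(table) == 4)
    x <- as.numeric(table)
  }
  if (any(x < 0) || any(x != round(x))) abort("counts must be non-negative integers")
  if (sum(x) == 0) abort("all-zero carrier table")
  stats::setNames(x, c("a", "b", "c", "d"))
}

# hypergeometric support and log point probabilities at odds ratio 1
hyper_support <- function(x) {
  m1 <- x["a"] + x["b"]  # cases
  m2 <- x["c"] + x["d"]  # controls
  k <- x["a"] + x["c"]   # carriers
  sup <- max(0, k - m2):min(k, m1)
  list(sup = sup, m1 = m1, m2 = m2, k = k,
       lw = lchoose(m1, sup) + lchoose(m2, k - sup))
}

# conditional (noncentral hypergeometric) pmf over the support at log-OR lp
cond_pmf <- function(h, lp) {
  ll <- h$lw + h$sup * lp
  ll <- ll - max(ll)
  p <- exp(ll)
  p / sum(p)
}

#' Fisher exact test for a carrier table
#'
#' Exact hypergeometric test of association in a 2x2 case/control carrier
#' table. The two-sided p-value uses the point-probability rule (sums all
#' tables with fixed margins whose probability does not exceed the observed
#' table's); the one-sided p-value sums the case-enrichment tail.
#'
#' @param table Carrier table (one-row tibble from [carrier_table()] or a
#'   numeric vector `c(case_carriers, case_noncarriers, control_carriers,
#'   control_noncarriers)`).
#' @return One-row tibble with `p_two_sided` and `p_one_sided`.
#' @export
#' @examples
#' fisher_exact(c(9, 314, 8, 1116))
fisher_exact <- function(table) {
  x <- as_counts(table)
  h <- hyper_support(x)
  d_obs <- dhyper(x["a"], h$m1, h$m2, h$k)
  d_all <- dhyper(h$sup, h$m1, h$m2, h$k)
  tibble::tibble(
    p_two_sided = min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)])),
    p_one_sided = min(1, sum(d_all[h$sup >= x["a"]]))
  )
}

#' Odds ratio and confidence interval for a carrier table
#'
#' Computes the odds ratio of carriage in cases versus controls, either as
#' the sample (cross-product) odds ratio or as the conditional maximum
#' likelihood estimate (CMLE) that maximises the noncentral hypergeometric
#' likelihood given the table margins -- the estimate reported by exact
#' tests. Confidence intervals are Woolf (log-normal) or exact conditional
#' (inversion of the one-sided exact tests at `alpha/2` per side; this is
#' the interval that accompanies the CMLE). Fisher exact p-values are
#' always attached.
#'
#' A table with an empty discordant cell has an infinite (or zero) odds
#' ratio; the default `zero_policy = "infinite"` reports it as such with
#' exact conditional bounds, `"haldane"` adds 0.5 to every cell for the
#' sample estimate and Woolf interval, and `"strict"` signals an error.
#'
#' @param table Carrier table as in [fisher_exact()].
#' @param method `"conditional_mle"` (default) or `"sample"`.
#' @param ci_method `"exact_conditional"` (default) or `"woolf"`.
#' @param zero_policy `"infinite"`, `"haldane"` or `"strict"`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble of class `assoc_result` with `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_two_sided`, `p_one_sided`, `method`,
#'   `ci_method`.
#' @export
#' @examples
#' odds_ratio(c(8, 171, 13, 959), method = "sample")
odds_ratio <- function(table,
                       method = c("conditional_mle", "sample"),
                       ci_method = c("exact_conditional", "woolf"),
                       zero_policy = c("infinite", "haldane", "strict"),
                       conf_level = 0.95) {
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  zero_policy <- match.arg(zero_policy)
  x <- as_counts(table)
  p <- fisher_exact(x)
  alpha <- 1 - conf_level

  zero_discordant <- (x["b"] * x["c"] == 0) || (x["a"] * x["d"] == 0)

  if (method == "sample") {
    if (zero_discordant && zero_policy == "strict") {
      abort("sample odds ratio undefined for a table with a zero cell (zero_policy = 'strict')")
    }
    xs <- if (zero_discordant && zero_policy == "haldane") x + 0.5 else x
    or <- unname((xs["a"] * xs["d"]) / (xs["b"] * xs["c"]))
  } else {
    or <- cmle_or(x)
  }

  if (ci_method == "woolf" && !(zero_discordant && zero_policy == "infinite")) {
    xs <- if (zero_discordant) x + 0.5 else x
    lo <- log((xs["a"] * xs["d"]) / (xs["b"] * xs["c"]))
    se <- sqrt(sum(1 / xs))
    z <- qnorm(1 - alpha / 2)
    ci <- unname(exp(lo + c(-z, z) * se))
  } else {
    ci <- exact_conditional_ci(x, alpha)
  }

  out <- tibble::tibble(
    odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
    p_two_sided = p$p_two_sided, p_one_sided = p$p_one_sided,
    method = method, ci_method = ci_method
  )
  class(out) <- c("assoc_result", class(out))
  out
}

# conditional MLE of the odds ratio: solve E_psi[X] = a on the log scale
cmle_or <- function(x) {
  h <- hyper_support(x)
  if (length(h$sup) == 1) return(NA_real_)  # degenerate margin: OR not estimable
  a <- unname(x["a"])
  if (a == max(h$sup)) return(Inf)
  if (a == min(h$sup)) return(0)
  f <- function(lp) sum(h$sup * cond_pmf(h, lp)) - a
  exp(uniroot(f, c(-40, 40), tol = 1e-10)$root)
}

# exact conditional CI by inverting the one-sided exact tests (alpha/2 each)
exact_conditional_ci <- function(x, alpha = 0.05) {
  h <- hyper_support(x)
  a <- unname(x["a"])
  if (length(h$sup) == 1) return(c(0, Inf))
  p_upper_tail <- function(lp) sum(cond_pmf(h, lp)[h$sup >= a])
  p_lower_tail <- function(lp) sum(cond_pmf(h, lp)[h$sup <= a])
  lo <- if (a == min(h$sup)) 0 else {
    exp(uniroot(function(lp) p_upper_tail(lp) - alpha / 2,
                c(-60, 60), tol = 1e-10)$root)
  }
  hi <- if (a == max(h$sup)) Inf else {
    exp(uniroot(function(lp) p_lower_tail(lp) - alpha / 2,
                c(-60, 60), tol = 1e-10)$root)
  }
  c(lo, hi)
}

#' @export
tidy.assoc_result <- function(x, ...) {
  tibble::tibble(
    term = "carrier",
    estimate = x$odds_ratio,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$p_two_sided
  )
}

#' @export
glance.assoc_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
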