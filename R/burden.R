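#' Per-sample rare-CNV burden summaries
#'
#' Tallies, for every sample in the sheet, the number of (already
#' rare-filtered) events and the total aneuploid sequence they span, within
#' a chromosome compartment and optionally one CNV class. Samples without
#' events get explicit zero rows, so the output always has one row per
#' sample and is invariant to the ordering or splitting of the call table.
#'
#' @param calls Consensus-call tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `cnv_class`), pre-filtered to the rare stratum of interest.
#' @param samples Sample sheet (`sample_id`, `status`, ...).
#' @param compartment `"genome"`, `"autosome"`, `"X"` or `"Y"`.
#' @param cnv_class Optional `"gain"`/`"loss"` restriction.
#' @param genome Genome manifest for compartment lookup.
#' @return Tibble `sample_id`, `status`, `compartment`, `cnv_class`,
#'   `n_events`, `aneuploid_bp`.
#' @export
summarize_burden <- function(calls, samples,
                             compartment = c("genome", "autosome", "X", "Y"),
                             cnv_class = NULL, genome = toy_genome()) {
  compartment <- match.arg(compartment)
  sub <- calls
  if (nrow(sub) > 0) {
    if (compartment != "genome") {
      sub <- sub[compartment_of(sub$chrom, genome) == compartment, ]
    }
    if (!is.null(cnv_class)) sub <- sub[sub$cnv_class == cnv_class, ]
  }
  per_sample <- sub |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      aneuploid_bp = sum(.data$end - .data$start),
      .groups = "drop"
    )
  samples |>
    dplyr::select("sample_id", dplyr::any_of("status")) |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      aneuploid_bp = dplyr::coalesce(.data$aneuploid_bp, 0),
      compartment = compartment,
      cnv_class = cnv_class %||% "any"
    ) |>
    dplyr::relocate("compartment", "cnv_class", .after = "sample_id")
}

#' Rank-sum test of burden between cases and controls
#'
#' Two-sided Mann-Whitney U test of a per-sample burden quantity (event
#' count or aneuploid bp). Uses the exact null distribution when both
#' groups have at most 50 observations and no ties are present, and the
#' tie-corrected normal approximation otherwise. Degenerate input in which
#' every value is identical gives p = 1.
#'
#' @param case_values,control_values Numeric vectors (both nonempty).
#' @return One-row tibble: `n_case`, `n_control`, `statistic` (U for the
#'   case group), `p_value`.
#' @export
ranksum_burden <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("both groups must be nonempty")
  }
  all_vals <- c(case_values, control_values)
  if (length(unique(all_vals)) == 1) {
    return(tibble::tibble(
      n_case = length(case_values), n_control = length(control_values),
      statistic = length(case_values) * length(control_values) / 2,
      p_value = 1
    ))
  }
  exact <- length(case_values) <= 50 && length(control_values) <= 50 &&
    !any(duplicated(all_vals))
  wt <- suppressWarnings(
    wilcox.test(case_values, control_values, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    n_case = length(case_values), n_control = length(control_values),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}

#' Logistic regression of case status on burden
#'
#' Fits `status ~ burden + covariates` by maximum likelihood, returning the
#' per-event log-odds with Wald confidence interval and p-value. Perfect or
#' quasi-perfect separation is detected and flagged rather than silently
#' returning a diverged fit; a Jeffreys-prior (Firth-style) penalised fit is
#' available as a fallback via `engine = "firth"`.
#'
#' @param data Tibble with a `status` column (`"case"`/`"control"`), the
#'   burden column named by `burden_col`, and any covariate columns.
#' @param burden_col Name of the burden column (default `"n_events"`).
#' @param covariates Character vector of covariate column names to adjust
#'   for (e.g. principal-component loadings); columns that are constant or
#'   collinear are dropped with a warning.
#' @param engine `"ml"` (default, via [stats::glm()]) or `"firth"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `burden_fit`: a list with elements `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`, `n_case`, `n_control`,
#'   `separation`, `covariate_betas`, `term`. Has [tidy()] and [glance()]
#'   methods.
#' @export
logistic_burden <- function(data, burden_col = "n_events",
                            covariates = character(),
                            engine = c("ml", "firth"),
                            conf_level = 0.95) {
  engine <- match.arg(engine)
  stopifnot(burden_col %in% names(data), "status" %in% names(data))
  y <- as.integer(data$status == "case")
  if (sum(y) == 0 || sum(1 - y) == 0) abort("need at least one case and one control")
  xb <- data[[burden_col]]
  if (all(xb == xb[1])) abort("degenerate design: burden column is constant")

  covariates <- intersect(covariates, names(data))
  X <- cbind(burden = xb)
  for (cv in covariates) {
    col <- data[[cv]]
    if (length(unique(col)) <= 1) {
      warn(paste0("dropping constant covariate ", cv))
      next
    }
    X <- cbind(X, stats::setNames(data.frame(col), cv))
  }
  X <- as.matrix(X)
  # drop collinear columns (keep burden first)
  qrX <- qr(cbind(1, X))
  keep <- qrX$pivot[seq_len(qrX$rank)]
  drop_cols <- setdiff(seq_len(ncol(X) + 1), keep)
  if (length(drop_cols) > 0) {
    drop_cols <- drop_cols[drop_cols > 1] - 1
    if (1 %in% drop_cols) abort("burden column collinear with covariates")
    warn(paste0("dropping collinear covariate(s): ",
                paste(colnames(X)[drop_cols], collapse = ", ")))
    X <- X[, -drop_cols, drop = FALSE]
  }

  if (engine == "firth") {
    fit <- firth_logistic(y, cbind(`(Intercept)` = 1, X))
    beta <- fit$coef["burden"]; se <- fit$se["burden"]
    covb <- fit$coef[setdiff(names(fit$coef), c("(Intercept)", "burden"))]
    separation <- FALSE
  } else {
    df <- data.frame(y = y, X)
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    cf <- coef(fit)
    se_all <- sqrt(diag(vcov(fit)))
    beta <- cf["burden"]; se <- se_all["burden"]
    covb <- cf[setdiff(names(cf), c("(Intercept)", "burden"))]
    separation <- sep_warn || abs(beta) > 15 || se > 100
    if (separation) {
      warn("possible separation in logistic burden fit; estimates unreliable (consider engine = 'firth')")
    }
  }

  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      term = burden_col,
      beta = unname(beta), se = unname(se),
      or = exp(unname(beta)),
      ci_low = exp(unname(beta) - z * se),
      ci_high = exp(unname(beta) + z * se),
      p = 2 * pnorm(-abs(unname(beta) / se)),
      n_case = sum(y), n_control = sum(1 - y),
      separation = separation,
      covariate_betas = covb,
      engine = engine
    ),
    class = "burden_fit"
  )
}

# Firth-style penalised logistic regression: Newton iterations on the
# Jeffreys-prior-modified score U*(b) = X'(y - mu + h * (0.5 - mu))
firth_logistic <- function(y, X, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * w))))
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)))
}

#' Combine burden estimates across cohorts
#'
#' Pools per-cohort burden effects into a single estimate. Because each
#' cohort in a multi-platform study is typed on its own array, a model with
#' cohort-level heterogeneity is required; two testable approximations of a
#' cohort-random-effect logistic model are provided: inverse-variance
#' meta-analysis of per-cohort log-odds (fixed effect, or DerSimonian-Laird
#' random effects) and a single stratified logistic fit with cohort
#' indicator covariates.
#'
#' @param fits For `"fixed_iv"`/`"random_iv"`: a list of `burden_fit`
#'   objects (one per cohort). For `"pooled_stratified"`: a tibble with
#'   `status`, a `cohort` column, the burden column and covariates, passed
#'   on to [logistic_burden()].
#' @param method `"random_iv"` (default), `"fixed_iv"` or
#'   `"pooled_stratified"`.
#' @param burden_col,covariates Passed to [logistic_burden()] for the
#'   stratified method.
#' @param conf_level Confidence level.
#' @return A `burden_fit` (subclass `burden_meta`) with an extra `tau2`
#'   element for the random-effects method and `cohort_fits` holding the
#'   inputs.
#' @export
combine_cohorts <- function(fits,
                            method = c("random_iv", "fixed_iv", "pooled_stratified"),
                            burden_col = "n_events", covariates = character(),
                            conf_level = 0.95) {
  method <- match.arg(method)
  if (method == "pooled_stratified") {
    stopifnot(is.data.frame(fits), "cohort" %in% names(fits))
    df <- fits
    df$cohort <- factor(df$cohort)
    cohort_dummies <- character()
    if (nlevels(df$cohort) > 1) {
      mm <- stats::model.matrix(~ cohort, df)[, -1, drop = FALSE]
      for (j in seq_len(ncol(mm))) df[[colnames(mm)[j]]] <- mm[, j]
      cohort_dummies <- colnames(mm)
    } else {
      warn("single cohort: stratified fit reduces to a plain logistic fit")
    }
    fit <- logistic_burden(df, burden_col = burden_col,
                           covariates = c(cohort_dummies, covariates),
                           conf_level = conf_level)
    fit$method <- method
    class(fit) <- c("burden_meta", class(fit))
    return(fit)
  }

  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "burden_fit")))
  if (length(fits) < 2) {
    warn("fewer than 2 cohorts: estimate passes through unchanged")
    fit <- fits[[1]]
    fit$method <- method
    fit$tau2 <- 0
    class(fit) <- c("burden_meta", class(fit))
    return(fit)
  }
  yi <- vapply(fits, `[[`, 0, "beta")
  sei <- vapply(fits, `[[`, 0, "se")
  rma_method <- if (method == "fixed_iv") "FE" else "DL"
  m <- metafor::rma(yi = yi, sei = sei, method = rma_method,
                    level = conf_level * 100)
  z <- qnorm(1 - (1 - conf_level) / 2)
  beta <- as.numeric(m$beta)
  se <- as.numeric(m$se)
  structure(
    list(
      term = fits[[1]]$term,
      beta = beta, se = se, or = exp(beta),
      ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
      p = as.numeric(m$pval),
      n_case = sum(vapply(fits, `[[`, 0, "n_case")),
      n_control = sum(vapply(fits, `[[`, 0, "n_control")),
      separation = any(vapply(fits, `[[`, TRUE, "separation")),
      tau2 = if (rma_method == "DL") as.numeric(m$tau2) else 0,
      method = method,
      cohort_fits = fits
    ),
    class = c("burden_meta", "burden_fit")
  )
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<", paste(class(x)[1]), "> ", x$term,
      if (!is.null(x$method)) paste0(" [", x$method, "]"), "\n", sep = "")
  cat(sprintf("  OR %.3f (%.3f-%.3f), p = %.3g, %d cases / %d controls\n",
              x$or, x$ci_low, x$ci_high, x$p, x$n_case, x$n_control))
  if (isTRUE(x$separation)) cat("  ! separation flagged\n")
  invisible(x)
}

#' @export
tidy.burden_fit <- function(x, ...) {
  tibble::tibble(
    term = x$term, estimate = x$beta, std.error = x$se,
    odds.ratio = x$or, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p
  )
}

#' @export
glance.burden_fit <- function(x, ...) {
  tibble::tibble(
    n_case = x$n_case, n_control = x$n_control,
    separation = x$separation,
    tau2 = x$tau2 %||% NA_real_,
    method = x$method %||% x$engine %||% "ml"
  )
}
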