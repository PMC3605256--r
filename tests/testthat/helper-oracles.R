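# Independent brute-force oracles used to check the analytical routines.
# These deliberately take the slow, enumerate-everything route.

# Exact p-values for a 2x2 table by explicit enumeration of all tables with
# the observed margins, using binomial coefficients directly.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  sup <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, sup) * choose(m2, k - sup) / choose(N, k)
  p_obs <- pr[sup == a]
  list(
    p_two = min(1, sum(pr[pr <= p_obs * (1 + 1e-7)])),
    p_one = min(1, sum(pr[sup >= a]))
  )
}

# Exact two-sided rank-sum p by enumeration of all assignments of the
# pooled ranks to the case group (tie-free data only).
oracle_ranksum <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  ranks <- rank(c(case_values, control_values))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  u_all <- apply(combos, 2, function(ix) sum(all_ranks[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Single-linkage connected components of the reciprocal-overlap graph,
# found by repeated sweeps (no sort order assumptions).
oracle_components <- function(start, end, threshold) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          reciprocal_overlap(start[i], end[i], start[j], end[j]) >= threshold) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Brute-force consensus on one sample's calls: components of the RO graph,
# kept when they contain >= min_alg distinct algorithms. Valid as an oracle
# on inputs whose components are cliques (well-separated jittered events).
oracle_consensus <- function(calls, min_alg = 2, threshold = 0.5) {
  out <- list()
  for (cls in unique(calls$cnv_class)) {
    for (ch in unique(calls$chrom)) {
      x <- calls[calls$cnv_class == cls & calls$chrom == ch, ]
      if (nrow(x) == 0) next
      comp <- oracle_components(x$start, x$end, threshold)
      for (g in unique(comp)) {
        m <- x[comp == g, ]
        if (length(unique(m$algorithm)) >= min_alg) {
          out[[length(out) + 1]] <- tibble::tibble(
            chrom = ch, cnv_class = cls,
            start = max(m$start), end = min(m$end),
            n_algorithms = length(unique(m$algorithm))
          )
        }
      }
    }
  }
  if (length(out) == 0) return(tibble::tibble())
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}
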