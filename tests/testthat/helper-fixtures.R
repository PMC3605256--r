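# Small fixtures built in code.

make_sheet <- function(n_case, n_control, cohort = "c1", platform = "p1",
                       prefix = cohort) {
  n <- n_case + n_control
  tibble::tibble(
    sample_id = sprintf("%s_s%03d", prefix, seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_control)),
    cohort = cohort, platform = platform
  )
}

make_call <- function(sample_id, chrom, start, end, cnv_class = "loss",
                      algorithm = "gada", platform = "p1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, cnv_class = cnv_class, algorithm = algorithm,
                 platform = platform)
}

# three jittered emissions of one true event, one per algorithm
jittered_event <- function(sample_id, chrom, start, end, jitter,
                           algorithms = c("a1", "a2", "a3"),
                           cnv_class = "loss") {
  dplyr::bind_rows(lapply(seq_along(algorithms), function(i) {
    make_call(sample_id, chrom, start + jitter[i], end + jitter[i],
              cnv_class, algorithms[i])
  }))
}
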