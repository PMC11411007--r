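# Results shared between acceptance blocks (computed once per test run).
.acceptance_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .acceptance_cache)) {
    assign(name, force(expr), envir = .acceptance_cache)
  }
  get(name, envir = .acceptance_cache)
}

# Count band implied by a reported count/total at the 99% level: propagate the
# Clopper-Pearson 99% interval of the reported proportion through the
# binomial quantiles of our own replication count.
count_band <- function(ref_count, ref_total, n_reps) {
  p_lo <- if (ref_count == 0) 0 else
    qbeta(0.005, ref_count, ref_total - ref_count + 1)
  p_hi <- if (ref_count == ref_total) 1 else
    qbeta(0.995, ref_count + 1, ref_total - ref_count)
  c(lower = qbinom(0.005, n_reps, p_lo), upper = qbinom(0.995, n_reps, p_hi))
}
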