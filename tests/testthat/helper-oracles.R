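# Independent oracles and small fixture builders shared across test files.

# Direct-enumeration oracle for the two-sided Fisher test: hypergeometric
# point probabilities over the support, minimum-likelihood rule. Uses
# stats::dhyper, an independent code path from the package's log-factorial
# implementation.
fisher_enum_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (min(r1, n - r1, c1, n - c1) == 0) return(1)
  aa <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(aa, c1, n - c1, r1)
  min(1, sum(probs[probs <= probs[aa == a] * (1 + rel_tol)]))
}

random_state_mixture <- function() {
  p <- stats::rgamma(4, 1)
  p <- p / sum(p)
  state_mixture(p[1], p[2], p[3], p[4])
}

# Tiny expression study built by hand: genes x (n_case + n_control)
make_study <- function(m, n_case, study_id = "T") {
  n <- ncol(m)
  samples <- data.frame(
    sample_id = colnames(m),
    group = rep(c("case", "control"), c(n_case, n - n_case)),
    stringsAsFactors = FALSE
  )
  expression_study(m, samples, study_id = study_id)
}

# Methylation-summary frame with given per-metric means (one row per
# sample), used for direct group-comparison simulations.
make_summaries <- function(n, means, sds) {
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (metric in names(means)) {
    out[[metric]] <- stats::rnorm(n, means[[metric]], sds[[metric]])
  }
  out
}
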