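# Independent oracles and small fixtures shared across test files.

# Brute-force per-read overlap check (1-based inclusive coordinates),
# deliberately naive so it stays independent of the GenomicRanges path.
brute_count <- function(reads, target, min_overlap = 1) {
  df <- if (inherits(reads, "read_alignment_set")) reads$reads else reads
  n <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != target$chrom) next
    ov <- min(df$end[i], target$end) - max(df$start[i], target$start) + 1L
    if (ov >= min_overlap) n <- n + 1L
  }
  n
}

# A minimal primary/test antibody pair with a chosen overlap fraction
# and (shared across isoforms) enhancement factor.
make_pair <- function(omega, e = 1, acc_primary = c(0.8, 0.9),
                      acc_test = c(0.7, 0.8)) {
  primary <- antibody_model("primary", acc_primary[1], acc_primary[2],
                            overlap = list(test = omega),
                            enhancer_of = if (e != 1)
                              list(test = c(e, e)) else list())
  test <- antibody_model("test", acc_test[1], acc_test[2],
                         overlap = list(primary = 0))
  list(primary = primary, test = test)
}

# Vectorised Welch t-test p-values for an m x n pair of group matrices
# (rows = simulated datasets). Used for the large null-calibration runs;
# cross-checked against welch_t_test() in test-stats.R.
welch_p_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(stat), df)
}

# Exact permutation p-value of the Welch statistic over all group
# relabellings (small samples only).
perm_welch_p <- function(a, b) {
  pooled <- c(a, b)
  idx <- combn(length(pooled), length(a))
  obs <- abs(welch_t_test(a, b)$statistic)
  stats <- apply(idx, 2, function(ii)
    abs(welch_t_test(pooled[ii], pooled[-ii])$statistic))
  mean(stats >= obs - 1e-12)
}
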