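# Independent plain-R Smith-Waterman (affine gaps) used to validate the
# package's aligner. A gap of length L scores gap_open + (L-1)*gap_extend;
# N matches nothing. Deliberately a separate code path from the package.
sw_oracle_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- -gap_open; ge <- -gap_extend
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)   # gap in A (consumes B)
  FF <- matrix(-Inf, n + 1L, m + 1L)  # gap in B (consumes A)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - go, E[i, j - 1L] - ge)
      FF[i, j] <- max(H[i - 1L, j] - go, FF[i - 1L, j] - ge)
      s <- if (A[i - 1L] == B[j - 1L] && A[i - 1L] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Mutate a sequence at exactly the given number of substitution sites
# (independent of the package's apply_divergence).
mutate_exact <- function(seq, n_subs) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(b), n_subs)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
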