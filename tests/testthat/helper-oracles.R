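# Independent oracles used to check the package's implementations.

# Plain Gotoh local-alignment DP (scores only), written independently of
# the package's aligner; gap of length L costs go + L*ge.
oracle_local_score <- function(q, r, match = 2, mism = -2, go = -3, ge = -1) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  m <- length(qc); n <- length(rc); NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] + go + ge, E[i - 1, j] + ge)
      F[i, j] <- max(H[i, j - 1] + go + ge, F[i, j - 1] + ge)
      s <- if (qc[i - 1] == rc[j - 1] && qc[i - 1] != "N") match else mism
      H[i, j] <- max(0, s + max(H[i - 1, j - 1], E[i - 1, j - 1],
                                F[i - 1, j - 1], 0))
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force D50: sort descending, scan every prefix, return the first
# prefix whose sum reaches half the total.
oracle_d50_C <- function(counts) {
  r <- sort(counts, decreasing = TRUE)
  J <- sum(r)
  acc <- 0
  for (i in seq_along(r)) {
    acc <- acc + r[i]
    if (acc >= J / 2) return(i)
  }
  stop("unreachable")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# random clonotype table for diversity / treemap property tests
random_clonotypes <- function(n, max_copies = 100) {
  data.frame(
    v_gene = sample(sprintf("IGHV%d-tst", 1:3), n, TRUE),
    j_gene = sample(sprintf("IGHJ%d-tst", 1:2), n, TRUE),
    cdr3_nt = vapply(seq_len(n), function(i) random_nt(sample(9:21, 1)),
                     character(1)),
    cdr3_aa = NA_character_,
    total_copies = sample(seq_len(max_copies), n, TRUE),
    n_unique = 1L,
    stringsAsFactors = FALSE)
}
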