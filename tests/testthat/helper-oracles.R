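# Independent oracles used to validate the package's metric and motif
# implementations. These deliberately use naive O(n^2) / exhaustive
# algorithms, not the code paths they check.

# Kendall tau-b by explicit enumeration of all pairs. Pairs tied in x
# (including pairs tied in both) count toward the x tie term, and
# likewise for y; concordance is only assessed on pairs untied in both.
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[i] - x[j])
      b <- sign(y[i] - y[j])
      if (a == 0) Tx <- Tx + 1
      if (b == 0) Ty <- Ty + 1
      if (a != 0 && b != 0) {
        if (a == b) C <- C + 1 else D <- D + 1
      }
    }
  }
  T0 <- n * (n - 1) / 2
  (C - D) / sqrt((T0 - Tx) * (T0 - Ty))
}

# Two-sample KS D by evaluating both empirical CDFs at every observed
# point and taking the largest gap.
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# AUROC as the fraction of (positive, negative) pairs ranked correctly,
# ties counting one half.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small synthetic configuration shared by tests that just need a valid
# multi-task dataset quickly.
tiny_cfg <- function(...) {
  args <- list(n_alleles = 2L, peptides_per_allele = 150L,
               n_proteins = 30L, decoys_per_hit = 4L, seed = 7L)
  user <- list(...)
  args[names(user)] <- user
  do.call(synth_config, args)
}

random_aa_string <- function(n, len, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(tlmhc:::AA_ALPHABET, len, replace = TRUE),
                           collapse = ""),
         character(1))
}
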