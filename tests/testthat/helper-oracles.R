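# Independent brute-force oracles and tiny fixture builders shared across
# tests. Oracles are deliberately naive (loops, enumeration) and never call
# the code paths they check.

# Benjamini-Hochberg by the textbook step-up definition
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  prev <- 1
  for (k in n:1) {
    i <- o[k]
    val <- min(prev, p[i] * n / k)
    adj[i] <- val
    prev <- val
  }
  adj
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_bruteforce <- function(n11, n10, n01, n00) {
  m1 <- n11 + n10   # row 1 total
  c1 <- n11 + n01   # col 1 total
  n <- n11 + n10 + n01 + n00
  lo <- max(0L, c1 - (n - m1)); hi <- min(m1, c1)
  probs <- vapply(lo:hi, function(k) stats::dhyper(k, m1, n - m1, c1), 0)
  obs <- stats::dhyper(n11, m1, n - m1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# empirical permutation p-value: (# null >= observed + 1) / (n + 1)
perm_p_bruteforce <- function(null, obs) (sum(null >= obs) + 1) / (length(null) + 1)

# per-sample mean squared distance from the column-mean composition
heterogeneity_bruteforce <- function(frac) {
  cm <- colMeans(frac)
  vapply(seq_len(nrow(frac)), function(s) mean((frac[s, ] - cm)^2), 0)
}

# probability-scale enumeration of colocalization posteriors: loops over
# every causal configuration, one causal variant per associated trait
coloc_bruteforce <- function(abf1, abf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(abf1)
  b1 <- exp(abf1); b2 <- exp(abf2)
  l0 <- 1
  l1 <- p1 * sum(b1)
  l2 <- p2 * sum(b2)
  l3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    l3 <- l3 + p1 * p2 * b1[i] * b2[j]
  l4 <- p12 * sum(b1 * b2)
  l <- c(l0, l1, l2, l3, l4)
  l / sum(l)
}

# small already-normalized dataset with clean, disjoint marker structure
make_tiny_sc <- function(n_types = 3, n_genes = 120, cells = 40,
                         markers = 10, lfc = 3, seed = 11) {
  sc <- simulate_scrna(n_types, n_genes, cells, markers, marker_log2fc = lfc,
                       seed = seed)
  lognormalize(sc)
}
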