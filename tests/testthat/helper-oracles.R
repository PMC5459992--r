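# Independent brute-force oracles, kept free of the package's own code paths.

# Two-sided Fisher p for table rbind(c(a, b), c(c, d)) by direct enumeration
# of the conditional distribution, probabilities from choose().
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + c; m2 <- b + d; k <- a + b; N <- m1 + m2
  if (m1 == 0 || m2 == 0 || N == 0) return(1)
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(N, k)
  pobs <- choose(m1, a) * choose(m2, k - a) / choose(N, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Benjamini-Hochberg by definition: q_(i) = min_{j >= i} m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric P(X >= k) by direct summation.
hyper_tail_oracle <- function(k, n_success, universe, n_draw) {
  xs <- k:min(n_success, n_draw)
  if (k > min(n_success, n_draw)) return(0)
  sum(choose(n_success, xs) * choose(universe - n_success, n_draw - xs) /
        choose(universe, n_draw))
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
ranksum_oracle <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  Wall <- apply(combn(n, na), 2, function(i) sum(r[i]))
  mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
}

# Tiny methyl_matrix builder: `levels` sites x samples in [0,1] (NA = no
# coverage), constant per-entry coverage `total`.
toy_matrix <- function(levels, total = 10, generation = NULL,
                       phenotype = NULL, pos = NULL) {
  levels <- as.matrix(levels)
  ns <- ncol(levels)
  if (is.null(generation)) generation <- rep("F0", ns)
  if (is.null(phenotype)) phenotype <- rep("Addict", ns)
  if (is.null(pos)) pos <- seq_len(nrow(levels)) * 100L
  tot <- matrix(total, nrow(levels), ns)
  tot[is.na(levels)] <- 0L
  meth <- round(ifelse(is.na(levels), 0, levels) * tot)
  methyl_matrix(
    sites = data.frame(chrom = "chr1", pos = pos),
    meth = matrix(as.integer(meth), nrow(levels)),
    total = matrix(as.integer(tot), nrow(levels)),
    samples = data.frame(sample_id = sprintf("S%02d", seq_len(ns)),
                         generation = generation, phenotype = phenotype,
                         stringsAsFactors = FALSE)
  )
}

# A 16-sample metadata layout matching the sperm study design.
study_layout <- function() {
  data.frame(
    sample_id = sprintf("S%02d", 1:16),
    generation = c(rep("F0", 10), rep("F1", 6)),
    phenotype = c(rep("Saline", 4), rep("Addict", 3), rep("Non-addict", 3),
                  rep("Addict", 3), rep("Non-addict", 3)),
    stringsAsFactors = FALSE
  )
}
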