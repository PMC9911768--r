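# Independent brute-force oracles shared across test files.

# independent brute-force oracle: explicit quantile bins, explicit
# contingency table, explicit Pearson statistic and chi-square tail
oracle_chi2_rank <- function(z, labels, candidates, n_bins = 10L) {
  lab <- as.integer(as.factor(labels))
  ps <- sapply(candidates, function(m) {
    x <- z[, m]
    qs <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1L), type = 7))
    b <- as.integer(cut(x, qs, include.lowest = TRUE))
    tab <- matrix(0, length(qs) - 1L, 2L)
    for (i in seq_along(x)) tab[b[i], lab[i]] <- tab[b[i], lab[i]] + 1L
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    pchisq(stat, (nrow(tab) - 1L) * (ncol(tab) - 1L), lower.tail = FALSE)
  })
  imp <- -log10(ps)
  candidates[order(-imp, candidates)]
}

# exhaustive oracle: best 2-partition by within-cluster cosine inertia
oracle_best_partition <- function(x) {
  xu <- x / sqrt(rowSums(x^2))
  S <- nrow(x)
  best <- NULL
  for (mask in 1:(2^(S - 1L) - 1L)) {
    lab <- as.integer(intToBits(mask))[seq_len(S)] + 1L
    if (length(unique(lab)) < 2L) next
    inertia <- 0
    for (j in 1:2) {
      m <- colMeans(xu[lab == j, , drop = FALSE])
      m <- m / sqrt(sum(m^2))
      inertia <- inertia + sum(1 - xu[lab == j, , drop = FALSE] %*% m)
    }
    if (is.null(best) || inertia < best$inertia - 1e-12)
      best <- list(lab = lab, inertia = inertia)
  }
  best
}
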