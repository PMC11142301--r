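# Independent oracles used across test files.

# Exhaustive re-derivation of the optimal-dimension rule, written as a
# literal loop so it cannot share bugs with the vectorized implementation.
dims_trace_oracle <- function(pv, cp_min = 90, pv_max = 5, delta = 0.1) {
  cp <- 0
  s2 <- NA
  for (i in seq_along(pv)) {
    cp <- cp + pv[i]
    if (is.na(s2) && cp > cp_min && pv[i] < pv_max) s2 <- i
  }
  s3 <- NA
  if (length(pv) > 1) {
    for (i in seq_len(length(pv) - 1)) {
      if (pv[i] - pv[i + 1] < delta) { s3 <- i; break }
    }
  }
  if (is.na(s2) && is.na(s3)) return(length(pv))
  min(s2, s3, na.rm = TRUE)
}

# brute-force Pearson correlation of two vectors
cor_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# best-match Jaccard of each planted module against a detected partition
jaccard_recovery <- function(partition, truth) {
  genes <- intersect(names(partition), names(truth))
  planted <- setdiff(unique(truth[genes]), "grey")
  det <- setdiff(unique(partition[genes]), "grey")
  vapply(planted, function(p) {
    tg <- genes[truth[genes] == p]
    if (!length(det)) return(0)
    max(vapply(det, function(d) {
      dg <- genes[partition[genes] == d]
      length(intersect(tg, dg)) / length(union(tg, dg))
    }, numeric(1)))
  }, numeric(1))
}

# adjusted Rand index between two labelings
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
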