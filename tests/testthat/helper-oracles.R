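# Independent oracles used across tests. These are deliberately naive
# (loops, enumeration, closed forms) and share no code with the package.

# triple-loop TOM, straight from the definition
tom_brute_force <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    ki <- sum(adj[i, -i])
    kj <- sum(adj[j, -j])
    out[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
  }
  out
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# n-subsets of an N-element universe containing a fixed K-subset
hyper_upper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # elements 1..K are the marked ones
  mean(hits >= k)
}

# Ward.D2 merge heights via the Lance-Williams recursion on raw distances
ward_d2_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  dd <- d
  diag(dd) <- Inf
  while (length(active) > 1) {
    sub <- dd[active, active, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(ij)]; j <- active[max(ij)]
    h <- dd[i, j]
    heights <- c(heights, h)
    for (m in active) {
      if (m == i || m == j) next
      ai <- (size[i] + size[m]) / (size[i] + size[j] + size[m])
      aj <- (size[j] + size[m]) / (size[i] + size[j] + size[m])
      b <- -size[m] / (size[i] + size[j] + size[m])
      dd[i, m] <- dd[m, i] <- sqrt(ai * dd[i, m]^2 + aj * dd[j, m]^2 +
                                     b * dd[i, j]^2)
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# brute-force exact KNN indices by all-pairs distances, index tie-break
knn_brute_force <- function(emb, k) {
  n <- nrow(emb)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(emb) - emb[i, ])^2))
    ord <- order(d, seq_len(n))
    setdiff(ord, i)[seq_len(k)]
  }, integer(k)))
}

# adjusted Rand index oracle (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
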