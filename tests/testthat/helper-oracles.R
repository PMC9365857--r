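# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from its definition and stay
# clear of the package's code paths.

# triple-loop topological overlap
bruteTOM <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# direct TMM between two samples: trimmed, weighted mean of M-values of obs
# relative to ref, genes with zero in either sample excluded
bruteTMMPair <- function(obs, ref, logratioTrim = 0.3, sumTrim = 0.05) {
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# full running-sum GSEA enrichment score via cumulative walk
bruteES <- function(stats, geneSet, weight = 1) {
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% geneSet
  N <- length(stats); nh <- sum(hit)
  inc <- numeric(N)
  aw <- abs(stats)^weight
  if (sum(aw[hit]) > 0) inc[hit] <- aw[hit] / sum(aw[hit]) else
    inc[hit] <- 1 / nh
  inc[!hit] <- -1 / (N - nh)
  walk <- cumsum(inc)
  if (max(walk) >= -min(walk) - 1e-12) max(walk) else min(walk)
}

# AUC by explicit pair counting with half-credit ties
bruteAUC <- function(x1, x2) {
  tot <- 0
  for (a in x1) for (b in x2)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x1) * length(x2))
}

# closed-form simple OLS slope/p of y on x
bruteOLS <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  b <- sum(xc * yc) / sum(xc^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sum(xc^2))
  list(slope = b, p = 2 * pt(abs(b / se), n - 2, lower.tail = FALSE))
}

# Jaccard of two sets
setJaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
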