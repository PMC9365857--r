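#' Log transcripts-per-10,000 normalisation
#'
#' \code{ln(count / cell_total * 1e4 + 1)} per cell; zero counts stay zero
#' and doubling every count in a cell leaves the values unchanged.
#'
#' @param counts genes-by-cells count matrix (sparse supported).
#' @return matrix of the same shape and class family.
#' @export
logTP10K <- function(counts) {
  m <- .asCountMatrix(counts)
  tot <- Matrix::colSums(m)
  tot[tot == 0] <- 1
  if (is(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    scale <- rep.int(1e4 / tot, diff(m@p))
    out <- m
    out@x <- log1p(m@x * scale)
    out
  } else {
    log1p(sweep(m, 2L, tot, `/`) * 1e4)
  }
}

#' Mann-Whitney AUC per gene between two cell groups
#'
#' Area under the ROC curve computed from midranks (ties handled by
#' averaging); 1 means perfectly higher in \code{group1}.
#'
#' @param x genes-by-cells expression matrix.
#' @param group1,group2 cell indices (or names) of the two groups.
#' @return named numeric vector of per-gene AUCs in [0,1].
#' @export
aucTest <- function(x, group1, group2) {
  x <- as.matrix(x)
  sub <- x[, c(group1, group2), drop = FALSE]
  n1 <- length(group1); n2 <- length(group2)
  rk <- matrixStats::rowRanks(sub, ties.method = "average")
  r1 <- rowSums(rk[, seq_len(n1), drop = FALSE])
  auc <- (r1 - n1 * (n1 + 1) / 2) / (n1 * n2)
  names(auc) <- rownames(x)
  auc
}

#' Bonferroni adjustment of marker p-values
#'
#' \code{min(1, p * n_tests)}, applied without flooring at the double
#' precision limit so that extreme marker p-values keep their printed
#' magnitude.
#'
#' @param p unadjusted p-values.
#' @param n_tests number of genes tested.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p, n_tests) pmin(1, p * n_tests)

# binomial log-likelihood contribution k*log(p) + (n-k)*log(1-p), 0log0 = 0
.binLL <- function(k, n, p) {
  ll <- numeric(length(k))
  pos <- k > 0
  ll[pos] <- k[pos] * log(p[pos])
  neg <- (n - k) > 0
  ll[neg] <- ll[neg] + (n - k)[neg] * log1p(-p[neg])
  ll
}

#' Two-part hurdle marker test of one cluster against the rest
#'
#' For every gene, combines (a) a binomial likelihood-ratio test on the
#' detection rate (expression > 0) and (b) a Gaussian likelihood-ratio test
#' on the mean of the positive log-TP10K values, into a single chi-square
#' statistic with 2 degrees of freedom. Reported per gene:
#' \code{p_val}; \code{avg_log2FC} =
#' \code{log2(mean(expm1(x)) in-cluster + 1) - log2(mean(expm1(x)) rest + 1)};
#' detection fractions \code{pct.1}/\code{pct.2}; and the Bonferroni-adjusted
#' \code{p_val_adj = min(1, p_val * n_genes)}. Rows are sorted by
#' \code{p_val}.
#'
#' @param log_tp10k genes-by-cells log-TP10K matrix (see
#'   \code{\link{logTP10K}}).
#' @param labels per-cell cluster labels.
#' @param cluster the cluster to test against all other cells combined; must
#'   contain at least 3 cells.
#' @return data.frame with columns \code{gene}, \code{p_val},
#'   \code{avg_log2FC}, \code{pct.1}, \code{pct.2}, \code{p_val_adj}.
#' @export
hurdleMarkers <- function(log_tp10k, labels, cluster) {
  m <- .asCountMatrix(log_tp10k)
  if (!cluster %in% labels) stop("cluster absent from labels")
  in1 <- labels == cluster
  n1 <- sum(in1); n2 <- sum(!in1)
  if (n1 < 3L) stop("cluster must contain at least 3 cells")
  G <- nrow(m)

  grp <- Matrix::sparseMatrix(i = seq_along(labels),
                              j = ifelse(in1, 1L, 2L), x = 1,
                              dims = c(length(labels), 2L))
  pos <- m
  if (is(pos, "sparseMatrix")) pos@x <- rep(1, length(pos@x)) else
    pos <- (pos > 0) * 1
  k <- as.matrix(pos %*% grp)          # detected cells per group
  s <- as.matrix(m %*% grp)            # sum of positive values per group
  m2 <- m; if (is(m2, "sparseMatrix")) m2@x <- m2@x^2 else m2 <- m2^2
  ss <- as.matrix(m2 %*% grp)          # sum of squares per group

  ## part (a): detection-rate binomial LRT
  p1 <- k[, 1] / n1; p2 <- k[, 2] / n2; p0 <- (k[, 1] + k[, 2]) / (n1 + n2)
  llFull <- .binLL(k[, 1], rep(n1, G), p1) + .binLL(k[, 2], rep(n2, G), p2)
  llNull <- .binLL(k[, 1] + k[, 2], rep(n1 + n2, G), p0)
  statDet <- 2 * (llFull - llNull)

  ## part (b): Gaussian LRT on positive values
  kt <- k[, 1] + k[, 2]
  rss1 <- pmax(ss[, 1] - s[, 1]^2 / pmax(k[, 1], 1), 0) +
    pmax(ss[, 2] - s[, 2]^2 / pmax(k[, 2], 1), 0)
  rss0 <- pmax(ss[, 1] + ss[, 2] - (s[, 1] + s[, 2])^2 / pmax(kt, 1), 0)
  ## guard against cancellation noise: sums of squares that cancel to
  ## ~machine precision mean the positive values are constant
  rssFloor <- 1e-10 * pmax(ss[, 1] + ss[, 2], .Machine$double.xmin)
  okCont <- k[, 1] >= 1 & k[, 2] >= 1 & kt >= 3 & rss0 > rssFloor
  statCont <- numeric(G)
  statCont[okCont] <- kt[okCont] *
    log(rss0[okCont] / pmax(rss1[okCont], rssFloor[okCont]))

  stat <- pmax(statDet, 0) + pmax(statCont, 0)
  pv <- pchisq(stat, df = 2, lower.tail = FALSE)

  ## fold change on the expm1 scale, means over all cells of each group
  me <- m
  if (is(me, "sparseMatrix")) me@x <- expm1(me@x) else me <- expm1(me)
  sm <- as.matrix(me %*% grp)
  lfc <- log2(sm[, 1] / n1 + 1) - log2(sm[, 2] / n2 + 1)

  out <- data.frame(gene = rownames(m), p_val = pv, avg_log2FC = lfc,
                    pct.1 = p1, pct.2 = p2,
                    p_val_adj = bonferroniAdjust(pv, G), row.names = NULL)
  out[order(out$p_val, -out$avg_log2FC, out$gene), , drop = FALSE]
}
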