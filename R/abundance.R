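#' Per-sample cluster proportions
#'
#' @param labels per-cell cluster labels.
#' @param samples per-cell sample labels.
#' @return samples-by-clusters matrix of fractions; rows sum to 1.
#' @export
clusterProportions <- function(labels, samples) {
  tab <- table(samples, labels)
  prop <- tab / rowSums(tab)
  out <- matrix(as.numeric(prop), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  names(dimnames(out)) <- NULL
  out
}

#' Univariate linear model of cluster abundance on gene expression
#'
#' Ordinary least squares of per-sample cluster abundance on the
#' (TMM-normalised, non-z-scored) pseudo-bulk expression of a single gene;
#' returns the regression coefficient and its two-sided t p-value.
#'
#' @param abundance per-sample cluster fractions.
#' @param expr per-sample expression of one gene.
#' @return list with \code{coefficient}, \code{p}, \code{r_squared}.
#' @export
abundanceUnivariate <- function(abundance, expr) {
  fit <- lm(abundance ~ expr)
  sm <- summary(fit)
  list(coefficient = unname(coef(fit)[2]),
       p = unname(sm$coefficients[2, 4]),
       r_squared = sm$r.squared)
}

#' Empirical-Bayes moderation of gene-wise residual variances
#'
#' Fits the scaled inverse-chi-square prior (d0, s0^2) to the observed
#' residual variances by moment matching on the log scale and returns the
#' posterior (shrunken) variances
#' \code{s2_post = (d0 s0^2 + df s2) / (d0 + df)}; an infinite d0 collapses
#' all variances to s0^2.
#'
#' @param s2 per-gene residual variances.
#' @param df_res residual degrees of freedom.
#' @return list with \code{d0}, \code{s0_sq}, \code{s2_post}.
#' @export
ebayesModerate <- function(s2, df_res) {
  s2 <- as.numeric(s2)
  if (length(s2) < 2L) {
    warning("too few genes for moderation; returning unmoderated variances")
    return(list(d0 = 0, s0_sq = NA_real_, s2_post = s2))
  }
  sq <- limma::squeezeVar(s2, df = df_res)
  list(d0 = sq$df.prior, s0_sq = sq$var.prior, s2_post = sq$var.post)
}

#' Genome-wide moderated scan of expression on cluster abundance
#'
#' Per gene, ordinary least squares of pseudo-bulk log expression on
#' per-sample abundance; residual variances are shrunk by
#' \code{\link{ebayesModerate}} and the moderated t statistic (with
#' \code{d0 + df_res} degrees of freedom) gives the p-value, adjusted across
#' genes by Benjamini-Hochberg. Constant genes are dropped with a warning.
#'
#' @param lognorm genes-by-samples log-normalised pseudo-bulk expression.
#' @param abundance per-sample cluster fractions (same order as columns).
#' @return data.frame with columns \code{gene}, \code{logFC} (slope),
#'   \code{t}, \code{p}, \code{fdr}, sorted by p.
#' @export
abundanceScan <- function(lognorm, abundance) {
  y <- as.matrix(lognorm)
  stopifnot(ncol(y) == length(abundance))
  keep <- matrixStats::rowSds(y) > .Machine$double.eps
  if (any(!keep)) {
    warning(sum(!keep), " constant genes dropped from the abundance scan")
    y <- y[keep, , drop = FALSE]
  }
  n <- ncol(y)
  x <- abundance - mean(abundance)
  sxx <- sum(x^2)
  beta <- as.vector(y %*% x) / sxx
  fitted <- outer(beta, x) + rowMeans(y)
  rss <- rowSums((y - fitted)^2)
  dfRes <- n - 2
  s2 <- rss / dfRes
  mod <- ebayesModerate(s2, dfRes)
  se <- sqrt(mod$s2_post / sxx)
  tstat <- beta / se
  dfTot <- mod$d0 + dfRes
  p <- 2 * pt(abs(tstat), df = dfTot, lower.tail = FALSE)
  out <- data.frame(gene = rownames(y), logFC = beta, t = tstat, p = p,
                    fdr = p.adjust(p, "BH"), row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

#' Build kNN neighbourhoods for differential abundance
#'
#' Samples index cells at \code{sample_fraction}, refines each index to the
#' member of its k-nearest-neighbour set closest to the neighbourhood
#' centroid, deduplicates, and defines each neighbourhood as the refined
#' index cell plus its k nearest neighbours in the first \code{n_pcs}
#' embedding dimensions. Per-sample member counts and the distance to the
#' kth neighbour (used by the spatial FDR) are recorded, along with the
#' majority cluster annotation when labels are supplied.
#'
#' @param scores cells-by-PCs embedding.
#' @param samples per-cell sample labels.
#' @param k neighbours per neighbourhood; default
#'   \code{clamp(n_cells/100, 20, 250)}.
#' @param n_pcs embedding dimensions used.
#' @param sample_fraction fraction of cells sampled as indices.
#' @param clusters optional per-cell cluster labels for the majority
#'   annotation.
#' @param seed RNG seed.
#' @return a \linkS4class{NeighbourhoodSet}.
#' @export
buildNeighbourhoods <- function(scores, samples, k = NULL, n_pcs = 4L,
                                sample_fraction = 0.1, clusters = NULL,
                                seed = 1L) {
  s <- as.matrix(scores)[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
  n <- nrow(s)
  if (is.null(k)) k <- as.integer(pmin(250, pmax(20, round(n / 100))))
  k <- min(k, n - 1L)
  set.seed(seed)
  idx0 <- sort(sample.int(n, max(1L, round(sample_fraction * n))))
  nn <- .knnIndices(s, k)
  refined <- vapply(idx0, function(i) {
    memb <- c(i, nn[i, ])
    ctr <- colMeans(s[memb, , drop = FALSE])
    d2 <- rowSums((s[memb, , drop = FALSE] -
                     rep(ctr, each = length(memb)))^2)
    memb[which.min(d2)]
  }, integer(1))
  refined <- sort(unique(refined))
  members <- lapply(refined, function(i) c(i, nn[i, ]))
  kth <- vapply(seq_along(refined), function(j) {
    i <- refined[j]
    sqrt(max(rowSums((s[nn[i, ], , drop = FALSE] -
                        rep(s[i, ], each = k))^2)))
  }, numeric(1))
  samples <- factor(samples)
  counts <- t(vapply(members, function(mb)
    tabulate(as.integer(samples)[mb], nbins = nlevels(samples)),
    integer(nlevels(samples))))
  colnames(counts) <- levels(samples)
  rownames(counts) <- paste0("nh", seq_along(refined))
  majCl <- character(0); majProp <- numeric(0)
  if (!is.null(clusters)) {
    clusters <- as.character(clusters)
    maj <- lapply(members, function(mb) {
      tb <- sort(table(clusters[mb]), decreasing = TRUE)
      c(names(tb)[1], unname(tb)[1] / length(mb))
    })
    majCl <- vapply(maj, `[`, "", 1L)
    majProp <- as.numeric(vapply(maj, `[`, "", 2L))
  }
  methods::new("NeighbourhoodSet", indexCells = refined, members = members,
               counts = counts, kthDistance = kth, majorityCluster = majCl,
               majorityProportion = majProp)
}

# moment estimator of a common NB dispersion phi across neighbourhoods:
# per neighbourhood-group combination, mean/variance of counts scaled to a
# common effective library; phi solves var = mu + phi mu^2 on average.
.commonDispersion <- function(counts, groups, eff) {
  phis <- c()
  rel <- sweep(counts, 2L, eff / mean(eff), `/`)
  for (g in levels(groups)) {
    sub <- rel[, groups == g, drop = FALSE]
    if (ncol(sub) < 2L) next
    mu <- rowMeans(sub)
    v <- matrixStats::rowVars(sub)
    ok <- mu > 0
    phis <- c(phis, (v[ok] - mu[ok]) / mu[ok]^2)
  }
  max(0, mean(phis, na.rm = TRUE))
}

#' Neighbourhood differential abundance test
#'
#' Per neighbourhood, a negative-binomial GLM of member counts on the
#' sample group, with an offset for the TMM-effective sample totals
#' (log(total cells x TMM factor)) and a common moment-estimated
#' dispersion; significance by likelihood-ratio chi-square. Multiplicity is
#' handled by a spatial FDR: Benjamini-Hochberg weighted by the reciprocal
#' kth-nearest-neighbour distance, so dense regions (small distances, high
#' weight) are corrected less harshly. Plain BH is available via
#' \code{spatial = FALSE}.
#'
#' @param nset a \linkS4class{NeighbourhoodSet}.
#' @param groups per-sample factor with levels \code{c("high","low")} (or
#'   any two levels; the second level's coefficient is reported).
#' @param spatial use distance-weighted BH.
#' @return data.frame with one row per neighbourhood: \code{nhood},
#'   \code{logFC} (log2 of the second-level effect), \code{p},
#'   \code{spatial_fdr}, plus the majority annotation when present.
#' @export
daTest <- function(nset, groups, spatial = TRUE) {
  counts <- nset@counts
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least two samples")
  stopifnot(length(groups) == ncol(counts))
  f <- tryCatch(tmmFactors(counts), error = function(e)
    rep(1, ncol(counts)))
  eff <- colSums(counts) * f
  off <- log(eff)
  phi <- .commonDispersion(counts, groups, eff)
  fam <- if (phi < 1e-8) stats::poisson() else
    MASS::negative.binomial(theta = 1 / phi)
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    fit1 <- glm(y ~ groups + offset(off), family = fam)
    fit0 <- glm(y ~ 1 + offset(off), family = fam)
    dev <- fit0$deviance - fit1$deviance
    pv <- pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
    c(coef(fit1)[2] / log(2), pv)
  }, numeric(2)))
  out <- data.frame(nhood = rownames(counts), logFC = res[, 1], p = res[, 2],
                    row.names = NULL)
  w <- if (spatial) 1 / pmax(nset@kthDistance, .Machine$double.eps) else
    rep(1, nrow(out))
  out$spatial_fdr <- weightedBH(out$p, w)
  if (length(nset@majorityCluster)) {
    out$majority_cluster <- nset@majorityCluster
    out$majority_proportion <- nset@majorityProportion
  }
  out
}

#' Weighted Benjamini-Hochberg adjustment
#'
#' Generalises BH with per-test weights: p-values are ordered and the jth
#' ordered p is scaled by \code{sum(w) / cumsum(w)[j]}, followed by the
#' usual step-up enforcement of monotonicity. Equal weights reduce to plain
#' BH.
#'
#' @param p p-values.
#' @param w positive weights (e.g. reciprocal kth-NN distances).
#' @return adjusted values, capped at 1.
#' @export
weightedBH <- function(p, w = rep(1, length(p))) {
  stopifnot(length(p) == length(w), all(w > 0))
  o <- order(p)
  adj <- sum(w) * p[o] / cumsum(w[o])
  adj <- rev(cummin(rev(adj)))
  out <- numeric(length(p))
  out[o] <- pmin(adj, 1)
  out
}

#' Filter neighbourhoods by majority-cluster purity
#'
#' Drops neighbourhoods whose majority-cluster proportion does not exceed
#' \code{min_majority} and flags the remainder as significant at
#' \code{spatial_fdr < alpha}.
#'
#' @param results output of \code{\link{daTest}} with majority annotation.
#' @param min_majority purity threshold (strictly greater than).
#' @param alpha spatial FDR significance level.
#' @return the filtered data.frame with a logical \code{significant} column.
#' @export
filterMajority <- function(results, min_majority = 0.8, alpha = 0.01) {
  stopifnot("majority_proportion" %in% colnames(results))
  out <- results[results$majority_proportion > min_majority, , drop = FALSE]
  out$significant <- out$spatial_fdr < alpha
  out
}
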