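# Running-sum enrichment score evaluated only at hit positions (the
# extremum of the walk is always attained immediately after a hit or
# immediately before the next hit), O(#hits) per evaluation.
# positions: sorted 1-based hit positions in the ranking; w: |stat|^weight
# at those positions (ranking order); N: ranking length.
.esFromPositions <- function(positions, w, N) {
  nh <- length(positions)
  miss <- 1 / (N - nh)
  wsum <- sum(w)
  if (wsum == 0) w <- rep(1 / nh, nh) else w <- w / wsum
  cumHit <- cumsum(w)
  ## value just after hit j: sum of hit weights so far minus miss penalty for
  ## the misses strictly before position j
  after <- cumHit - (positions - seq_len(nh)) * miss
  ## value just before hit j: all misses up to position j-1, hits before j
  before <- c(0, cumHit[-nh]) - (positions - seq_len(nh)) * miss
  lo <- min(before, after)
  hi <- max(after, 0)
  ## the positive extremum wins exact-magnitude ties
  pos <- hi >= -lo - 1e-12
  es <- if (pos) hi else lo
  attr(es, "peak") <- if (pos) positions[which.max(after)] else
    positions[which.min(before)]
  es
}

#' Preranked gene set enrichment with a gene-set-sampling null
#'
#' Walks the ranking from top to bottom, incrementing by
#' \eqn{|s|^{weight}/\sum_{hits}|s|^{weight}} at gene-set hits and
#' decrementing by \eqn{1/(N - N_{hit})} at misses; the enrichment score is
#' the extremum of the running sum. The null distribution is obtained by
#' drawing \code{n_perm} random gene sets of the same size from the ranked
#' universe; NES is the ES divided by the mean magnitude of same-sign null
#' scores, and the p-value counts same-sign null scores at least as extreme,
#' with +1 smoothing on both numerator and denominator.
#'
#' @param stats named numeric vector of per-gene ranking statistics.
#' @param gene_set character vector; its intersection with
#'   \code{names(stats)} must be nonempty and proper.
#' @param n_perm number of null gene-set draws.
#' @param weight exponent on the hit increments (0 = unweighted).
#' @param seed RNG seed for the null draws.
#' @return list with \code{es}, \code{nes}, \code{p}, \code{leading_edge}
#'   and \code{n_hits}.
#' @export
prerankedGSEA <- function(stats, gene_set, n_perm = 10000L, weight = 1,
                          seed = 1L) {
  stats <- sort(stats, decreasing = TRUE)
  N <- length(stats)
  hits <- which(names(stats) %in% gene_set)
  if (length(hits) == 0L) stop("gene set does not intersect the ranking")
  if (length(hits) >= N) stop("gene set must be a proper subset of the ranking")
  nh <- length(hits)
  aw <- abs(stats)^weight
  es <- .esFromPositions(hits, aw[hits], N)
  peak <- attr(es, "peak")
  es <- as.numeric(es)
  set.seed(seed)
  nullES <- vapply(seq_len(n_perm), function(i) {
    pos <- sort(sample.int(N, nh))
    as.numeric(.esFromPositions(pos, aw[pos], N))
  }, numeric(1))
  same <- nullES[sign(nullES) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  le <- if (es >= 0) names(stats)[hits[hits <= peak]] else
    names(stats)[hits[hits >= peak]]
  list(es = es, nes = nes, p = p, leading_edge = le, n_hits = nh)
}

#' Preranked GSEA over several gene sets with BH adjustment
#'
#' @param stats named numeric ranking statistics.
#' @param gene_sets named list of gene sets.
#' @param ... passed to \code{\link{prerankedGSEA}}.
#' @return data.frame with one row per set: \code{set}, \code{es},
#'   \code{nes}, \code{p}, \code{padj}, \code{n_hits}.
#' @export
prerankedGSEAMulti <- function(stats, gene_sets, ...) {
  res <- lapply(gene_sets, function(gs) prerankedGSEA(stats, gs, ...))
  out <- data.frame(
    set = names(gene_sets),
    es = vapply(res, `[[`, 0, "es"),
    nes = vapply(res, `[[`, 0, "nes"),
    p = vapply(res, `[[`, 0, "p"),
    n_hits = vapply(res, function(r) as.numeric(r$n_hits), 0),
    row.names = NULL)
  out$padj <- p.adjust(out$p, "BH")
  out
}
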