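#' Variance-stabilised per-gene variability statistics
#'
#' Fits a loess curve of log10(variance) on log10(mean) over genes with
#' positive variance, standardises each gene by the fitted standard
#' deviation, clips the standardised values at sqrt(n_cells) and reports the
#' variance of the clipped values (the "standardised variance") alongside
#' the raw mean and variance.
#'
#' @param counts genes-by-cells raw count matrix.
#' @param span loess span for the mean-variance trend.
#' @return data.frame with columns \code{mean}, \code{variance},
#'   \code{variance_standardized}, rownames = gene ids.
#' @export
vstStats <- function(counts, span = 0.3) {
  m <- .asCountMatrix(counts)
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  vs <- rep(0, length(mu))
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 10) {
    fit <- suppressWarnings(loess(log10(v[ok]) ~ log10(mu[ok]), span = span,
                                  degree = 2))
    sdFit <- sqrt(10^suppressWarnings(predict(fit)))
    clipMax <- sqrt(n)
    dense <- as.matrix(m[ok, , drop = FALSE])
    z <- (dense - mu[ok]) / sdFit
    z[z > clipMax] <- clipMax
    z[z < -clipMax] <- -clipMax
    vs[ok] <- matrixStats::rowVars(z)
  }
  data.frame(mean = mu, variance = v, variance_standardized = vs,
             row.names = rownames(m))
}

#' Select highly variable genes by standardised variance
#'
#' Genes are ranked by the variance-stabilised standardised variance of
#' \code{\link{vstStats}}; ties are broken by gene id so the selection is
#' deterministic.
#'
#' @param counts genes-by-cells raw count matrix.
#' @param n number of genes to return (must not exceed the gene count).
#' @return character vector of the top-\code{n} gene ids, most variable
#'   first.
#' @export
selectHVG <- function(counts, n = 5000L) {
  m <- .asCountMatrix(counts)
  if (n > nrow(m)) stop("n exceeds the number of genes")
  st <- vstStats(m)
  o <- order(-st$variance_standardized, rownames(st))
  rownames(st)[o][seq_len(n)]
}

#' Principal-component embedding of cells
#'
#' Columns (genes) are centred and unit-scaled (constant genes are left
#' centred only), then scores are computed from the eigendecomposition of
#' the smaller-dimension covariance. Component signs are fixed by making the
#' largest-magnitude loading entry of each component positive, so the
#' embedding is deterministic.
#'
#' @param x cells-by-genes expression matrix (e.g. log-normalised HVGs).
#' @param n_pcs number of components.
#' @param scale. scale genes to unit variance before the decomposition.
#' @return list with \code{scores} (cells x PCs), \code{loadings}
#'   (genes x PCs) and \code{sdev}.
#' @export
embedPCA <- function(x, n_pcs = 50L, scale. = TRUE) {
  x <- as.matrix(x)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  if (scale.) {
    s <- matrixStats::colSds(x)
    s[s <= .Machine$double.eps] <- 1
    xc <- sweep(xc, 2L, s, `/`)
  }
  if (ncol(xc) <= nrow(xc)) {
    cv <- crossprod(xc) / max(nrow(xc) - 1L, 1L)
    eg <- eigen(cv, symmetric = TRUE)
    rot <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    sdev <- sqrt(pmax(eg$values[seq_len(n_pcs)], 0))
  } else {
    gram <- tcrossprod(xc) / max(nrow(xc) - 1L, 1L)
    eg <- eigen(gram, symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(n_pcs)], 0)
    u <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    rot <- crossprod(xc, u)
    nrm <- sqrt(colSums(rot^2))
    nrm[nrm == 0] <- 1
    rot <- sweep(rot, 2L, nrm, `/`)
    sdev <- sqrt(lam)
  }
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- xc %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  rownames(scores) <- rownames(x)
  list(scores = scores, loadings = rot, sdev = sdev)
}

# k nearest neighbours (excluding self) from a score matrix; returns an
# n x k index matrix. Distance computed blockwise to bound memory.
.knnIndices <- function(scores, k, block = 1000L) {
  n <- nrow(scores)
  k <- min(k, n - 1L)
  sq <- rowSums(scores^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * tcrossprod(scores[idx, , drop = FALSE],
                                                   scores)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' Shared-nearest-neighbour graph with Jaccard weights
#'
#' Builds the k-nearest-neighbour set of every cell (the cell itself plus
#' its k nearest neighbours) and connects cells by the Jaccard overlap of
#' their neighbour sets; pairs with no shared neighbours get no edge, and
#' the graph carries no self-edges.
#'
#' @param scores cells-by-PCs embedding.
#' @param k neighbours per cell.
#' @param prune drop edges with Jaccard weight below this value.
#' @return an undirected weighted \code{igraph} graph on the cells.
#' @export
snnGraph <- function(scores, k, prune = 0) {
  n <- nrow(scores)
  nn <- .knnIndices(as.matrix(scores), k)
  k <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                              j = as.vector(rbind(seq_len(n), t(nn))), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  s <- shared@x[keep]
  w <- s / (2 * (k + 1L) - s)
  ok <- w > prune
  g <- igraph::graph_from_edgelist(cbind(i[ok], j[ok]), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w[ok])
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::set_vertex_attr(g, "name", value = rownames(scores))
}

#' Louvain community detection with size-ordered labels
#'
#' Runs modularity-based Louvain clustering at the given resolution and
#' relabels communities 0..K-1 by decreasing size. With a fixed seed the
#' result is deterministic.
#'
#' @param graph weighted undirected \code{igraph} graph.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed.
#' @return integer vector of 0-based contiguous cluster labels, named by
#'   vertex when the graph is named.
#' @export
findClustersLouvain <- function(graph, resolution = 0.6, seed = 1L) {
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(memb)])
  names(out) <- igraph::V(graph)$name
  out
}

#' Merge transcriptionally indistinguishable clusters
#'
#' For every cluster pair, counts the genes whose two-sided AUC
#' (\code{max(AUC, 1 - AUC)}) between the two clusters is at least
#' \code{auc_min}; pairs separated by fewer than \code{max_de} such genes
#' are merged (closest pair first), and the procedure repeats until no pair
#' qualifies. Labels are relabelled contiguously by decreasing size.
#'
#' @param labels per-cell cluster labels.
#' @param log_tp10k genes-by-cells log-TP10K matrix.
#' @param auc_min two-sided AUC cutoff defining a discriminating gene.
#' @param max_de minimum number of discriminating genes that keeps a pair
#'   separate.
#' @return integer vector of merged 0-based labels with the merged pairs in
#'   attribute \code{"merged_pairs"}.
#' @export
mergeSimilarClusters <- function(labels, log_tp10k, auc_min = 0.6,
                                 max_de = 30L) {
  labels <- as.integer(factor(labels)) - 1L
  m <- as.matrix(log_tp10k)
  stopifnot(length(labels) == ncol(m))
  merged <- list()
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2L) break
    best <- NULL
    bestCount <- Inf
    for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1):length(ids)) {
      c1 <- which(labels == ids[a]); c2 <- which(labels == ids[b])
      auc <- aucTest(m, c1, c2)
      cnt <- sum(pmax(auc, 1 - auc) >= auc_min)
      if (cnt < bestCount) { bestCount <- cnt; best <- c(ids[a], ids[b]) }
    }
    if (bestCount >= max_de) break
    merged[[length(merged) + 1L]] <- best
    labels[labels == best[2]] <- best[1]
  }
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(labels)])
  names(out) <- colnames(m)
  attr(out, "merged_pairs") <- merged
  out
}

#' Cluster cells end to end
#'
#' Convenience driver: highly variable genes on raw counts, log-TP10K
#' expression, PCA embedding, shared-nearest-neighbour graph, Louvain
#' communities and the marker-AUC merge rule.
#'
#' @param sce \linkS4class{SingleCellExperiment} (or genes-by-cells counts).
#' @param n_hvg number of variable genes.
#' @param n_pcs number of principal components.
#' @param k neighbours for the SNN graph; default scales with cohort size as
#'   \code{clamp(n_cells / 50, 20, 250)}.
#' @param resolution Louvain resolution.
#' @param seed RNG seed.
#' @param merge apply the merge rule.
#' @return list with \code{labels} (0-based), \code{scores} (PCA), the
#'   \code{hvg} set and the graph.
#' @export
clusterCells <- function(sce, n_hvg = 1000L, n_pcs = 50L, k = NULL,
                         resolution = 0.6, seed = 1L, merge = TRUE) {
  counts <- .asCountMatrix(sce)
  n <- ncol(counts)
  if (is.null(k)) k <- as.integer(pmin(250, pmax(20, round(n / 50))))
  hvg <- selectHVG(counts, min(n_hvg, nrow(counts)))
  tp <- logTP10K(counts)
  pca <- embedPCA(t(as.matrix(tp[hvg, , drop = FALSE])), n_pcs = n_pcs)
  g <- snnGraph(pca$scores, k)
  labels <- findClustersLouvain(g, resolution = resolution, seed = seed)
  if (merge && length(unique(labels)) > 1L)
    labels <- mergeSimilarClusters(labels, tp)
  list(labels = labels, scores = pca$scores, hvg = hvg, graph = g)
}
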