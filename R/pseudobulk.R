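#' Sum single-cell counts to pseudo-bulk units
#'
#' Sums the counts of every gene over all cells of each unit, where a unit is
#' a sample (\code{by = "sample"}) or a sample-within-cluster combination
#' (\code{by = "sample_cluster"}). The grand total is conserved exactly.
#'
#' @param counts genes-by-cells count matrix (sparse or dense).
#' @param sample per-cell sample labels.
#' @param cluster per-cell cluster labels (required for
#'   \code{by = "sample_cluster"}).
#' @param by aggregation unit.
#' @return genes-by-units dense matrix of summed counts; for cluster mode the
#'   unit names are \code{"<sample>.<cluster>"} with the mapping in
#'   attributes \code{"sample"} and \code{"cluster"}.
#' @export
aggregateCounts <- function(counts, sample, cluster = NULL,
                            by = c("sample", "sample_cluster")) {
  by <- match.arg(by)
  m <- .asCountMatrix(counts)
  if (length(sample) != ncol(m) || anyNA(sample))
    stop("every cell needs a sample label")
  if (by == "sample_cluster") {
    if (is.null(cluster) || length(cluster) != ncol(m) || anyNA(cluster))
      stop("cluster mode requires per-cell cluster labels")
    unit <- interaction(sample, cluster, drop = TRUE, lex.order = TRUE)
  } else unit <- factor(sample)
  design <- Matrix::sparseMatrix(
    i = seq_len(ncol(m)), j = as.integer(unit), x = 1,
    dims = c(ncol(m), nlevels(unit)))
  out <- as.matrix(m %*% design)
  colnames(out) <- levels(unit)
  rownames(out) <- rownames(m)
  if (by == "sample_cluster") {
    parts <- strsplit(levels(unit), ".", fixed = TRUE)
    attr(out, "sample") <- vapply(parts, `[`, "", 1L)
    attr(out, "cluster") <- vapply(parts, function(p)
      paste(p[-1L], collapse = "."), "")
  }
  out
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Between-sample scaling factors robust to composition bias: pairwise
#' log-ratios against a reference column (the one whose 75th percentile is
#' closest to the mean 75th percentile) are trimmed by 30% on M and 5% on A
#' and averaged with precision weights. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts genes-by-samples count matrix with at least two samples and
#'   no all-zero sample.
#' @return numeric vector of per-sample factors.
#' @export
tmmFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  f <- f / .geomMean(f)
  names(f) <- colnames(counts)
  f
}

#' Log-normalise pseudo-bulk counts with TMM-scaled library sizes
#'
#' \code{log2(count / (lib_size * factor) * 1e6 + 0.5)}: counts per million
#' on the TMM-effective library, with a 0.5-CPM pseudocount.
#'
#' @param counts genes-by-samples count matrix.
#' @param factors per-sample TMM factors (default: computed).
#' @param offset pseudocount on the CPM scale.
#' @return genes-by-samples matrix of log2 normalised expression.
#' @export
logNormalize <- function(counts, factors = tmmFactors(counts), offset = 0.5) {
  counts <- as.matrix(counts)
  eff <- colSums(counts) * factors
  log2(sweep(counts, 2L, eff, `/`) * 1e6 + offset)
}

#' Standardise each gene across units
#'
#' Each row is centred and scaled by its sample (n-1) standard deviation.
#' Zero-variance genes become all-zero rows and are reported in the
#' \code{"zero_variance"} attribute. Applying the function twice is a no-op.
#'
#' @param lognorm genes-by-units matrix.
#' @return z-scored matrix of the same shape.
#' @export
zscoreGenes <- function(lognorm) zscoreRows(as.matrix(lognorm))

#' Build a PseudobulkExperiment from single-cell counts
#'
#' Aggregates cells to units (see \code{\link{aggregateCounts}}), computes
#' TMM factors, the log2-CPM view and the per-gene z-score view, and wraps
#' them in a \linkS4class{PseudobulkExperiment}.
#'
#' @param x a \linkS4class{SingleCellExperiment} (with colData columns named
#'   by \code{sampleCol}/\code{clusterCol}) or a genes-by-cells matrix.
#' @param by aggregation unit.
#' @param sampleCol,clusterCol colData column names holding the labels.
#' @param sample,cluster explicit per-cell labels (override colData).
#' @return a \linkS4class{PseudobulkExperiment}.
#' @export
pseudobulk <- function(x, by = c("sample", "sample_cluster"),
                       sampleCol = "sample", clusterCol = "cluster",
                       sample = NULL, cluster = NULL) {
  by <- match.arg(by)
  if (is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(sample)) sample <- cd[[sampleCol]]
    if (is.null(cluster) && clusterCol %in% colnames(cd))
      cluster <- cd[[clusterCol]]
  }
  agg <- aggregateCounts(x, sample, cluster, by)
  f <- tmmFactors(agg)
  ln <- logNormalize(agg, f)
  z <- zscoreGenes(ln)
  cd <- S4Vectors::DataFrame(tmm_factor = f, lib_size = colSums(agg),
                             row.names = colnames(agg))
  if (by == "sample_cluster") {
    cd$sample <- attr(agg, "sample")
    cd$cluster <- attr(agg, "cluster")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = `attributes<-`(agg, attributes(agg)[c("dim", "dimnames")]),
                  lognorm = ln,
                  zscore = `attributes<-`(z, attributes(z)[c("dim", "dimnames")])),
    colData = cd,
    rowData = S4Vectors::DataFrame(
      zero_variance = rownames(agg) %in% attr(z, "zero_variance"),
      row.names = rownames(agg)))
  methods::new("PseudobulkExperiment", se)
}
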