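#' Barcode-rank inflection threshold for empty-droplet removal
#'
#' Orders barcodes by decreasing total UMI count and locates the point of
#' steepest negative slope of the 3-point moving-average smoothed
#' log10(count) versus log10(rank) curve. The returned threshold is the
#' geometric midpoint of the smoothed counts flanking the steepest segment;
#' barcodes with total count below it are called empty.
#'
#' @param umi named numeric vector of per-barcode total UMI counts.
#' @param min_barcodes minimum number of nonzero barcodes required.
#' @return the UMI threshold (barcodes with count >= threshold are retained),
#'   with the retained barcode names in attribute \code{"retained"}.
#' @export
barcodeRankInflection <- function(umi, min_barcodes = 100L) {
  umi <- umi[umi > 0]
  if (length(umi) < min_barcodes)
    stop("too few barcodes with nonzero counts")
  o <- order(umi, decreasing = TRUE)
  x <- log10(seq_along(o))
  y <- log10(umi[o])
  n <- length(y)
  sm <- y
  sm[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  slope <- diff(sm) / diff(x)
  if (all(slope >= -1e-12)) stop("no inflection found")
  i <- which.min(slope)
  thr <- 10^((sm[i] + sm[i + 1]) / 2)
  keep <- names(umi)[umi >= thr]
  structure(thr, retained = keep)
}

#' Remove genes expressed in fewer than \code{min_cells} cells
#'
#' @param counts genes-by-cells count matrix (or SingleCellExperiment).
#' @param min_cells minimum number of cells with nonzero expression; genes in
#'   exactly \code{min_cells} cells are retained.
#' @return the input with failing genes dropped (order preserved).
#' @export
filterGenesMinCells <- function(counts, min_cells = 20L) {
  m <- .asCountMatrix(counts)
  keep <- Matrix::rowSums(m > 0) >= min_cells
  counts[keep, , drop = FALSE]
}

#' Remove cells whose expression sparsity exceeds a cutoff
#'
#' Sparsity is the fraction of genes with zero count in the cell; cells with
#' sparsity strictly greater than \code{max_sparsity} are removed (a cell at
#' exactly the cutoff is retained).
#'
#' @param counts genes-by-cells count matrix (or SingleCellExperiment).
#' @param max_sparsity maximum allowed zero-gene fraction.
#' @return the input with failing cells dropped.
#' @export
filterCellsSparsity <- function(counts, max_sparsity = 0.99) {
  m <- .asCountMatrix(counts)
  sparsity <- 1 - Matrix::colSums(m > 0) / nrow(m)
  counts[, sparsity <= max_sparsity, drop = FALSE]
}

#' Remove cells with outlying mitochondrial expression
#'
#' A cell is removed iff its mitochondrial count proportion exceeds
#' \code{median + k * MAD} of the per-cell proportions. The MAD is unscaled
#' (no 1.4826 consistency factor) and the cut is one-sided: only high
#' mitochondrial content marks damaged cells.
#'
#' @param counts genes-by-cells count matrix (or SingleCellExperiment).
#' @param mito_genes character vector of mitochondrial gene ids (nonempty).
#' @param k MAD multiplier; \code{Inf} disables the filter.
#' @return the input with failing cells dropped.
#' @export
filterCellsMito <- function(counts, mito_genes, k = 2.5) {
  m <- .asCountMatrix(counts)
  mito_genes <- intersect(mito_genes, rownames(m))
  if (length(mito_genes) == 0L) stop("empty mitochondrial gene set")
  tot <- Matrix::colSums(m)
  prop <- Matrix::colSums(m[mito_genes, , drop = FALSE]) / pmax(tot, 1)
  med <- median(prop)
  madU <- median(abs(prop - med))
  keep <- if (is.infinite(k)) rep(TRUE, length(prop)) else
    prop <= med + k * madU
  counts[, keep, drop = FALSE]
}

#' Run the four-step droplet/cell/gene quality-control cascade
#'
#' Applies, in order: (i) empty-droplet removal at the barcode-rank
#' inflection, (ii) removal of genes expressed in fewer than
#' \code{min_cells} cells, (iii) removal of cells with expression sparsity
#' above \code{max_sparsity}, (iv) removal of cells whose mitochondrial
#' proportion lies more than \code{mito_k} unscaled MADs above the median.
#'
#' @param sce a \linkS4class{SingleCellExperiment} (or count matrix).
#' @param mito_prefix prefix identifying mitochondrial gene names.
#' @param min_cells,max_sparsity,mito_k filter parameters.
#' @param inflection apply the empty-droplet step (skip for pre-filtered
#'   matrices with too few barcodes).
#' @return list with the filtered object (\code{$filtered}) and a
#'   \code{$report} list (class \code{QCReport}) of counts in/out per step.
#' @export
runQC <- function(sce, mito_prefix = "MT-", min_cells = 20L,
                  max_sparsity = 0.99, mito_k = 2.5, inflection = TRUE) {
  m0 <- .asCountMatrix(sce)
  nIn <- ncol(m0)
  inflThr <- NA_real_
  x <- sce
  if (inflection) {
    umi <- Matrix::colSums(m0)
    names(umi) <- colnames(m0)
    thr <- tryCatch(barcodeRankInflection(umi), error = function(e) NULL)
    if (!is.null(thr)) {
      inflThr <- as.numeric(thr)
      x <- x[, colnames(m0) %in% attr(thr, "retained"), drop = FALSE]
    }
  }
  nDroplet <- ncol(.asCountMatrix(x))
  gIn <- nrow(m0)
  x <- filterGenesMinCells(x, min_cells)
  gOut <- nrow(.asCountMatrix(x))
  x <- filterCellsSparsity(x, max_sparsity)
  nSpars <- ncol(.asCountMatrix(x))
  mito <- grep(paste0("^", mito_prefix), rownames(.asCountMatrix(x)),
               value = TRUE)
  if (length(mito) && is.finite(mito_k)) x <- filterCellsMito(x, mito, mito_k)
  nOut <- ncol(.asCountMatrix(x))
  report <- structure(list(
    n_barcodes_in = nIn, n_barcodes_out = nOut,
    inflection_threshold = inflThr,
    cells_removed_empty = nIn - nDroplet,
    genes_removed = gIn - gOut,
    cells_removed_sparsity = nDroplet - nSpars,
    cells_removed_mito = nSpars - nOut), class = "QCReport")
  list(filtered = x, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QCReport:", x$n_barcodes_in, "barcodes in ->", x$n_barcodes_out,
      "cells out\n")
  cat("  empty droplets removed:", x$cells_removed_empty,
      if (is.na(x$inflection_threshold)) "(no inflection)" else
        sprintf("(threshold %.1f UMIs)", x$inflection_threshold), "\n")
  cat("  genes removed:", x$genes_removed,
      "| sparsity removals:", x$cells_removed_sparsity,
      "| mito removals:", x$cells_removed_mito, "\n")
  invisible(x)
}
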