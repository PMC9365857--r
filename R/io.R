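#' Write a cohort to a CellRanger-style Matrix Market fixture
#'
#' Emits \code{matrix.mtx} (1-based triplet of nonzeros), \code{barcodes.tsv},
#' \code{features.tsv}, a per-cell \code{metadata.tsv} (sample and, when
#' available, true cluster labels) and, when the object carries simulation
#' ground truth, \code{truth_samples.tsv} and \code{truth_module.tsv}. The
#' files round-trip losslessly through \code{\link{readFixture}}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
writeFixture <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- .asCountMatrix(sce)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                            "metadata.tsv"))
  Matrix::writeMM(m, paths[1])
  writeLines(colnames(m), paths[2])
  writeLines(rownames(m), paths[3])
  cd <- data.frame(barcode = colnames(m))
  if (is(sce, "SummarizedExperiment")) {
    meta <- as.data.frame(SummarizedExperiment::colData(sce))
    for (col in intersect(c("sample", "cluster_true"), colnames(meta)))
      cd[[col]] <- meta[[col]]
    truth <- S4Vectors::metadata(sce)$truth
    if (!is.null(truth)) {
      ts <- data.frame(sample = names(truth$sample_driver_activity),
                       driver_activity = unname(truth$sample_driver_activity),
                       rare_abundance = unname(truth$per_sample_rare_abundance))
      p <- file.path(dir, "truth_samples.tsv")
      write.table(ts, p, sep = "\t", quote = FALSE, row.names = FALSE)
      pm <- file.path(dir, "truth_module.tsv")
      writeLines(truth$module_members, pm)
      paths <- c(paths, p, pm)
    }
  }
  write.table(cd, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a Matrix Market fixture back into a SingleCellExperiment
#'
#' @param dir directory written by \code{\link{writeFixture}} (or any
#'   CellRanger-style triplet plus optional \code{metadata.tsv}).
#' @return a \linkS4class{SingleCellExperiment}.
#' @export
readFixture <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  cdPath <- file.path(dir, "metadata.tsv")
  cd <- if (file.exists(cdPath)) {
    meta <- read.table(cdPath, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    rownames(meta) <- meta$barcode
    S4Vectors::DataFrame(meta[colnames(m), -1L, drop = FALSE])
  } else S4Vectors::DataFrame(row.names = colnames(m))
  md <- list()
  tsPath <- file.path(dir, "truth_samples.tsv")
  if (file.exists(tsPath)) {
    ts <- read.table(tsPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    md$truth <- list(
      sample_driver_activity = setNames(ts$driver_activity, ts$sample),
      per_sample_rare_abundance = setNames(ts$rare_abundance, ts$sample),
      module_members = readLines(file.path(dir, "truth_module.tsv")))
  }
  if ("sample" %in% colnames(cd)) cd$sample <- factor(cd$sample)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd, metadata = md)
}
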