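#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' PseudobulkExperiment: per-unit summed counts with TMM-normalised views
#'
#' Extends \linkS4class{SummarizedExperiment} with three assays on a
#' genes-by-units layout (a unit is a sample, or a sample-within-cluster
#' combination): \code{counts} (summed UMIs), \code{lognorm}
#' (log2 CPM using TMM-scaled library sizes) and \code{zscore} (each gene
#' standardised across units with the sample, n-1, standard deviation).
#' Per-unit TMM factors and library sizes live in \code{colData}; genes whose
#' lognorm values are constant across units are flagged in
#' \code{rowData(x)$zero_variance}.
#'
#' @seealso \code{\link{pseudobulk}}
#' @export
setClass("PseudobulkExperiment", contains = "SummarizedExperiment")

setValidity("PseudobulkExperiment", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "lognorm", "zscore") %in% an))
    msg <- c(msg, "assays must include 'counts', 'lognorm' and 'zscore'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("tmm_factor", "lib_size") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'tmm_factor' and 'lib_size'")
  else {
    f <- cd$tmm_factor
    if (any(f <= 0)) msg <- c(msg, "tmm_factor must be positive")
    else if (abs(log(.geomMean(f))) > 1e-6)
      msg <- c(msg, "tmm_factor must have geometric mean 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' CoexprNetwork: a signed weighted co-expression network
#'
#' Holds the gene-gene Pearson correlation, the signed adjacency
#' \eqn{a_{ij} = ((1+cor_{ij})/2)^\beta}, the topological overlap matrix,
#' the average-linkage dendrogram on 1-TOM, per-gene module labels
#' (colour-coded, \code{"grey"} = unassigned) and the sample-by-module
#' eigengene matrix (each eigengene has unit norm over samples).
#'
#' @seealso \code{\link{runCoexpression}}
#' @export
setClass("CoexprNetwork", representation(
  correlation = "matrix",
  beta = "numeric",
  adjacency = "matrix",
  tom = "matrix",
  dendrogram = "ANY",
  modules = "character",
  eigengenes = "matrix",
  powerTable = "data.frame"
))

setValidity("CoexprNetwork", function(object) {
  msg <- NULL
  a <- object@adjacency
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  else {
    if (max(abs(a - t(a))) > 1e-8) msg <- c(msg, "adjacency must be symmetric")
    if (any(abs(diag(a) - 1) > 1e-8)) msg <- c(msg, "adjacency diagonal must be 1")
    if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
      msg <- c(msg, "adjacency entries must lie in [0,1]")
  }
  tm <- object@tom
  if (length(tm) && (min(tm) < -1e-12 || max(tm) > 1 + 1e-8))
    msg <- c(msg, "TOM entries must lie in [0,1]")
  if (length(object@modules) < nrow(a) ||
      !all(rownames(a) %in% names(object@modules)))
    msg <- c(msg, "one module label per network gene required")
  if (ncol(object@eigengenes) > 0) {
    nrm <- sqrt(colSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigengene columns must have unit norm over samples")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn CoexprNetwork per-gene module labels (named character vector)
#' @param x,object a \code{CoexprNetwork}
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @export
setMethod("moduleLabels", "CoexprNetwork", function(x) x@modules)

#' @describeIn CoexprNetwork sample-by-module eigengene matrix
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))
#' @export
setMethod("moduleEigengenes", "CoexprNetwork", function(x) x@eigengenes)

#' @describeIn CoexprNetwork signed adjacency matrix
#' @export
setGeneric("networkAdjacency", function(x) standardGeneric("networkAdjacency"))
#' @export
setMethod("networkAdjacency", "CoexprNetwork", function(x) x@adjacency)

#' @describeIn CoexprNetwork topological overlap matrix
#' @export
setGeneric("networkTOM", function(x) standardGeneric("networkTOM"))
#' @export
setMethod("networkTOM", "CoexprNetwork", function(x) x@tom)

#' @describeIn CoexprNetwork selected soft-threshold power
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))
#' @export
setMethod("softPower", "CoexprNetwork", function(x) x@beta)

setMethod("show", "CoexprNetwork", function(object) {
  tab <- table(object@modules)
  cat("CoexprNetwork:", nrow(object@adjacency), "genes, beta =", object@beta, "\n")
  cat("  modules:", paste0(names(tab), "(", tab, ")", collapse = " "), "\n")
  cat("  eigengenes:", ncol(object@eigengenes), "modules x",
      nrow(object@eigengenes), "samples\n")
})

#' NeighbourhoodSet: kNN neighbourhoods for differential abundance
#'
#' Each neighbourhood is the k nearest cells (in a low-dimensional embedding)
#' around a refined index cell. Slots hold the index cells, member lists, the
#' neighbourhood-by-sample count matrix, the distance to the kth nearest
#' neighbour (used for the spatial FDR), and the majority-cluster annotation.
#'
#' @seealso \code{\link{buildNeighbourhoods}}, \code{\link{daTest}}
#' @export
setClass("NeighbourhoodSet", representation(
  indexCells = "integer",
  members = "list",
  counts = "matrix",
  kthDistance = "numeric",
  majorityCluster = "character",
  majorityProportion = "numeric"
))

setValidity("NeighbourhoodSet", function(object) {
  msg <- NULL
  n <- length(object@indexCells)
  if (length(object@members) != n || nrow(object@counts) != n ||
      length(object@kthDistance) != n)
    msg <- c(msg, "per-neighbourhood slots must have equal length")
  if (any(vapply(object@members, length, 1L) == 0L))
    msg <- c(msg, "member sets must be nonempty")
  if (length(object@majorityProportion) &&
      (any(object@majorityProportion <= 0) || any(object@majorityProportion > 1)))
    msg <- c(msg, "majorityProportion must lie in (0,1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "NeighbourhoodSet", function(object) {
  cat("NeighbourhoodSet:", length(object@indexCells), "neighbourhoods over",
      ncol(object@counts), "samples\n")
  cat("  median size:", median(vapply(object@members, length, 1L)), "cells\n")
})

#' SampleGrouping: a two-group sample partition with its permutation null
#'
#' The partition labels samples \code{high}/\code{low} by the root split of a
#' complete-linkage dendrogram over hub-gene z-scores; \code{empiricalP} is
#' the fraction of random same-size gene draws that reproduce the identical
#' unordered bipartition.
#'
#' @seealso \code{\link{groupSamplesByHubGenes}},
#'   \code{\link{groupingPermutationP}}
#' @export
setClass("SampleGrouping", representation(
  partition = "factor",
  nMatches = "integer",
  nPerm = "integer",
  empiricalP = "numeric"
))

setValidity("SampleGrouping", function(object) {
  msg <- NULL
  if (nlevels(object@partition) != 2L || any(table(object@partition) == 0L))
    msg <- c(msg, "partition must have two nonempty groups")
  if (length(object@nPerm) && object@nPerm > 0L &&
      abs(object@empiricalP - object@nMatches / object@nPerm) > 1e-12)
    msg <- c(msg, "empiricalP must equal nMatches/nPerm")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SampleGrouping", function(object) {
  cat("SampleGrouping:", paste(table(object@partition), collapse = " vs "),
      "samples\n")
  if (length(object@nPerm) && object@nPerm > 0L)
    cat("  permutation null:", object@nMatches, "/", object@nPerm,
        "matches, empirical p =", object@empiricalP, "\n")
})

#' @describeIn SampleGrouping the high/low partition as a named factor
#' @param x a \code{SampleGrouping}
#' @export
setGeneric("groupingPartition", function(x) standardGeneric("groupingPartition"))
#' @export
setMethod("groupingPartition", "SampleGrouping", function(x) x@partition)

#' @describeIn SampleGrouping empirical permutation p-value
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))
#' @export
setMethod("empiricalP", "SampleGrouping", function(x) x@empiricalP)
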