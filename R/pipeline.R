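#' Pipeline run configuration
#'
#' Collects every stage toggle and tunable parameter of
#' \code{\link{runPipeline}} with defaults matching the published analysis:
#' gene filter at 20 cells, sparsity 0.99, mito cut 2.5 MADs, Louvain
#' resolution 0.6, up to 5000 variable genes for intra-cluster networks,
#' module merge height 0.25, hub thresholds MM/kIM/adjacency 0.7/0.7/0.3,
#' auxiliary thresholds GS/GS-p/MM 0.5/0.05/0.5, 10,000 grouping
#' permutations, majority proportion 0.8 and spatial FDR 0.01.
#'
#' @param seed mandatory integer seed; fanned out per stage so toggling one
#'   stage does not shift another's randomness.
#' @param ... overrides for any default listed above (see
#'   \code{formals(pipelineConfig)}).
#' @param stages character vector of stages to run.
#' @param min_cells,max_sparsity,mito_k QC parameters.
#' @param k_snn,resolution,n_hvg_cluster clustering parameters
#'   (\code{k_snn = NULL} scales with cohort size).
#' @param pan_power,intra_power soft powers (\code{"auto"} or integer).
#' @param min_module_size,merge_height module detection parameters.
#' @param hub_mm,hub_kim,hub_adj hub-gene thresholds.
#' @param aux_gs,aux_gs_p,aux_mm auxiliary-module thresholds.
#' @param n_perm_grouping,n_perm_gsea permutation counts.
#' @param k_da,n_pcs_da,nhood_fraction neighbourhood parameters.
#' @param min_majority,spatial_alpha DA filtering parameters.
#' @return a validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(seed,
                           stages = c("qc", "cluster", "pan_network",
                                      "markers", "enrichment", "grouping",
                                      "intra_network", "preservation",
                                      "variability", "abundance", "da"),
                           min_cells = 20L, max_sparsity = 0.99,
                           mito_k = 2.5, k_snn = NULL, resolution = 0.6,
                           n_hvg_cluster = 1000L, pan_power = "auto",
                           intra_power = 6, min_module_size = 30L,
                           merge_height = 0.25, hub_mm = 0.7, hub_kim = 0.7,
                           hub_adj = 0.3, aux_gs = 0.5, aux_gs_p = 0.05,
                           aux_mm = 0.5, n_perm_grouping = 10000L,
                           n_perm_gsea = 10000L, k_da = NULL, n_pcs_da = 4L,
                           nhood_fraction = 0.1, min_majority = 0.8,
                           spatial_alpha = 0.01, ...) {
  if (missing(seed)) stop("seed is mandatory")
  extra <- list(...)
  if (length(extra)) stop("unknown config fields: ",
                          paste(names(extra), collapse = ", "))
  stopifnot(max_sparsity > 0, max_sparsity <= 1, min_majority >= 0,
            min_majority <= 1, spatial_alpha > 0, spatial_alpha < 1,
            hub_mm >= 0, hub_kim >= 0, hub_adj >= 0)
  cfg <- as.list(environment())
  cfg$extra <- NULL
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full cluster-specificity analysis
#'
#' Orchestrates, on a multi-sample single-cell cohort: quality control,
#' graph-based clustering, the pan-cluster co-expression network on
#' per-sample pseudo-bulk with module-trait statistics against the driver,
#' cluster markers with target-set enrichment, hub-gene sample grouping with
#' its permutation null, the intra-cluster network of the target-rich
#' cluster, auxiliary-module preservation across clusters, per-cluster
#' variability of the targets, and abundance modelling (per-gene moderated
#' scan plus neighbourhood differential abundance between the sample
#' groups). The target-rich candidate cluster is the one with the highest
#' mean target-gene log-TP10K expression.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a per-cell
#'   \code{sample} column (e.g. from \code{\link{generateCohort}} or
#'   \code{\link{readFixture}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param target_genes trans-eQTL target gene ids; defaults to the planted
#'   module when the object carries simulation truth.
#' @param driver_gene driver (cis-target) gene id; defaults to the planted
#'   driver.
#' @param labels optional named per-cell cluster labels, used by
#'   cluster-dependent stages when the \code{cluster} stage is disabled
#'   (e.g. to run downstream stages on known annotations).
#' @param out_dir optional directory; stage tables are written as TSV and a
#'   markdown summary as \code{summary.md}.
#' @param verbose log stage progress and surviving dimensions to stderr.
#' @return a named list of stage artifacts (class \code{PipelineResult}).
#' @export
runPipeline <- function(sce, config, target_genes = NULL, driver_gene = NULL,
                        labels = NULL, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  truth <- S4Vectors::metadata(sce)$truth
  if (is.null(target_genes)) target_genes <- truth$module_members
  if (is.null(driver_gene)) driver_gene <- truth$driver_gene
  if (is.null(target_genes) || is.null(driver_gene))
    stop("target_genes and driver_gene are required when no truth is attached")
  st <- config$stages
  res <- list(config = config)

  if ("qc" %in% st) {
    qc <- runQC(sce, min_cells = config$min_cells,
                max_sparsity = config$max_sparsity, mito_k = config$mito_k)
    sce <- qc$filtered
    res$qc <- qc$report
    say("qc: ", qc$report$n_barcodes_out, " cells, ",
        nrow(sce), " genes retained")
  }
  counts <- .asCountMatrix(sce)
  samples <- SummarizedExperiment::colData(sce)$sample
  if (is.null(samples)) stop("stage dependency violation: no 'sample' labels")
  target_genes <- intersect(target_genes, rownames(counts))
  tp10k <- logTP10K(counts)

  scores <- NULL
  if ("cluster" %in% st) {
    cl <- clusterCells(sce, n_hvg = min(config$n_hvg_cluster, nrow(counts)),
                       k = config$k_snn, resolution = config$resolution,
                       seed = stageSeed(config$seed, "cluster"))
    labels <- cl$labels
    scores <- cl$scores
    res$clusters <- labels
    say("cluster: ", length(unique(labels)), " clusters")
  } else if (!is.null(labels)) {
    labels <- labels[colnames(counts)]
    if (anyNA(labels)) stop("supplied labels do not cover all cells")
  }

  pbSample <- pseudobulk(counts, by = "sample", sample = samples)
  zs <- SummarizedExperiment::assay(pbSample, "zscore")
  ln <- SummarizedExperiment::assay(pbSample, "lognorm")
  res$pseudobulk <- pbSample
  driverExpr <- if (driver_gene %in% rownames(ln)) ln[driver_gene, ] else
    stop("driver gene absent after QC")

  panNet <- NULL
  panStats <- NULL
  if ("pan_network" %in% st) {
    panNet <- runCoexpression(zs, power = config$pan_power,
                              min_module_size = config$min_module_size,
                              merge_height = config$merge_height)
    panStats <- geneStatistics(zs, panNet, driverExpr)
    mt <- moduleTraitCor(moduleEigengenes(panNet),
                         data.frame(driver = driverExpr))
    res$pan_network <- panNet
    res$pan_stats <- panStats
    res$module_trait <- mt
    say("pan_network: beta ", softPower(panNet), ", ",
        ncol(moduleEigengenes(panNet)), " modules")
  }

  markers <- NULL
  rareCandidate <- NULL
  if ("markers" %in% st) {
    if (is.null(labels))
      stop("stage dependency violation: 'markers' requires 'cluster'")
    meansByCluster <- vapply(sort(unique(labels)), function(cl)
      mean(Matrix::rowMeans(tp10k[target_genes, labels == cl,
                                  drop = FALSE])), numeric(1))
    rareCandidate <- sort(unique(labels))[which.max(meansByCluster)]
    markers <- hurdleMarkers(tp10k, labels, rareCandidate)
    res$markers <- markers
    res$rare_candidate <- rareCandidate
    say("markers: candidate cluster ", rareCandidate)
  }

  if ("enrichment" %in% st) {
    if (is.null(markers))
      stop("stage dependency violation: 'enrichment' requires 'markers'")
    rk <- setNames(markers$avg_log2FC, markers$gene)
    res$marker_enrichment <- prerankedGSEA(
      rk, target_genes, n_perm = config$n_perm_gsea,
      seed = stageSeed(config$seed, "enrichment"))
    if (!is.null(panNet)) {
      dm <- .driverModule(panNet, moduleTraitCor(
        moduleEigengenes(panNet), data.frame(driver = driverExpr)))
      if (!is.na(dm)) {
        inMod <- names(moduleLabels(panNet))[moduleLabels(panNet) == dm]
        mm <- setNames(panStats$MM, panStats$gene)[inMod]
        mm <- mm[!is.na(mm)]
        if (sum(names(mm) %in% target_genes) > 0 &&
            sum(!names(mm) %in% target_genes) > 0)
          res$module_enrichment <- prerankedGSEA(
            mm, target_genes, n_perm = config$n_perm_gsea,
            seed = stageSeed(config$seed, "enrichment"))
      }
    }
    say("enrichment: marker-ranking p = ", res$marker_enrichment$p)
  }

  grouping <- NULL
  if ("grouping" %in% st) {
    if (is.null(panNet))
      stop("stage dependency violation: 'grouping' requires 'pan_network'")
    dm <- .driverModule(panNet, res$module_trait)
    if (is.na(dm)) stop("no module correlated with the driver")
    hubs <- hubGenes(panStats, module = dm, mm_min = config$hub_mm,
                     kim_min = config$hub_kim, adj_min = config$hub_adj)
    if (length(hubs) < 2L) stop("fewer than 2 hub genes at the thresholds")
    part <- groupSamplesByHubGenes(zs, hubs)
    grouping <- groupingPermutationP(
      zs, part, n_perm = config$n_perm_grouping,
      seed = stageSeed(config$seed, "grouping"))
    res$hub_genes <- hubs
    res$grouping <- grouping
    say("grouping: ", length(hubs), " hubs, empirical p = ",
        empiricalP(grouping))
  }

  pbCluster <- NULL
  pbByCluster <- NULL
  if (any(c("intra_network", "preservation", "variability") %in% st)) {
    if (is.null(labels))
      stop("stage dependency violation: cluster-level stages require 'cluster'")
    pbCluster <- pseudobulk(counts, by = "sample_cluster", sample = samples,
                            cluster = labels)
    zAll <- SummarizedExperiment::assay(pbCluster, "zscore")
    unitCl <- SummarizedExperiment::colData(pbCluster)$cluster
    pbByCluster <- lapply(
      setNames(nm = sort(unique(as.character(labels)))),
      function(cl) zAll[, unitCl == cl, drop = FALSE])
  }

  intraNet <- NULL
  intraStats <- NULL
  if ("intra_network" %in% st) {
    if (is.null(rareCandidate))
      stop("stage dependency violation: 'intra_network' requires 'markers'")
    zRare <- pbByCluster[[as.character(rareCandidate)]]
    rareCells <- counts[, labels == rareCandidate, drop = FALSE]
    nHVG <- min(5000L, nrow(rareCells))
    hv <- selectHVG(rareCells, nHVG)
    ## no kME refinement here: the auxiliary-module selection applies its
    ## own GS/MM filter to the (typically broad) intra-cluster module,
    ## so sharp module boundaries are not required at this stage
    intraNet <- runCoexpression(zRare[hv, , drop = FALSE],
                                power = config$intra_power,
                                min_module_size = config$min_module_size,
                                merge_height = config$merge_height,
                                kme_refine_p = NULL)
    drv <- if (driver_gene %in% rownames(zRare))
      zRare[driver_gene, ] else driverExpr
    intraStats <- geneStatistics(zRare[hv, , drop = FALSE], intraNet, drv)
    res$intra_network <- intraNet
    res$intra_stats <- intraStats
    say("intra_network: ", ncol(moduleEigengenes(intraNet)), " modules")
  }

  if ("preservation" %in% st) {
    if (is.null(intraStats))
      stop("stage dependency violation: 'preservation' requires 'intra_network'")
    aux <- defineAuxiliaryModule(intraStats, target_genes,
                                 gs_min = config$aux_gs,
                                 gs_p_max = config$aux_gs_p,
                                 mm_min = config$aux_mm)
    res$auxiliary_module <- aux
    if (length(aux) >= 2L) {
      res$preservation <- preservationCorKME(
        pbByCluster, as.character(rareCandidate), aux)
      res$correlation_panels <- pairwiseCorrelationPanel(
        pbByCluster, c(aux, driver_gene))
      say("preservation: ", length(aux), " auxiliary genes")
    } else say("preservation skipped: auxiliary module too small")
  }

  if ("variability" %in% st) {
    res$variability <- perClusterVariability(
      counts, samples, labels, genes = intersect(
        c(target_genes, driver_gene), rownames(counts)))
  }

  if ("abundance" %in% st) {
    if (is.null(labels))
      stop("stage dependency violation: 'abundance' requires 'cluster'")
    props <- clusterProportions(labels, samples)
    ab <- props[colnames(ln), as.character(rareCandidate)]
    res$abundance <- ab
    res$abundance_univariate <- abundanceUnivariate(ab, driverExpr)
    res$abundance_scan <- abundanceScan(ln, ab)
    say("abundance: driver coefficient ",
        signif(res$abundance_univariate$coefficient, 3))
  }

  if ("da" %in% st) {
    if (is.null(grouping) || is.null(scores))
      stop("stage dependency violation: 'da' requires 'grouping' and 'cluster'")
    part <- groupingPartition(grouping)
    if (any(table(part) < 2L)) {
      res$da_skipped <- "degenerate grouping: a group has fewer than 2 samples"
      say("da skipped: ", res$da_skipped)
      class(res) <- "PipelineResult"
      if (!is.null(out_dir)) .writePipelineOutputs(res, out_dir)
      return(res)
    }
    nset <- buildNeighbourhoods(scores, samples, k = config$k_da,
                                n_pcs = config$n_pcs_da,
                                sample_fraction = config$nhood_fraction,
                                clusters = labels,
                                seed = stageSeed(config$seed, "da"))
    part <- part[colnames(nset@counts)]
    daRes <- daTest(nset, part)
    res$neighbourhoods <- nset
    res$da <- daRes
    res$da_filtered <- filterMajority(daRes,
                                      min_majority = config$min_majority,
                                      alpha = config$spatial_alpha)
    say("da: ", nrow(res$da_filtered), " majority-pure neighbourhoods")
  }

  class(res) <- "PipelineResult"
  if (!is.null(out_dir)) .writePipelineOutputs(res, out_dir)
  res
}

# module whose eigengene is most significantly correlated with the driver
.driverModule <- function(network, mt) {
  if (is.null(mt) || !"driver" %in% colnames(mt$cor)) return(NA_character_)
  if (nrow(mt$cor) == 0L) return(NA_character_)
  rownames(mt$cor)[which.max(abs(mt$cor[, "driver"]))]
}

.writePipelineOutputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  if (!is.null(res$markers)) wt(res$markers, "markers.tsv")
  if (!is.null(res$pan_stats)) wt(res$pan_stats, "pan_gene_stats.tsv")
  if (!is.null(res$intra_stats)) wt(res$intra_stats, "intra_gene_stats.tsv")
  if (!is.null(res$preservation)) wt(res$preservation, "preservation.tsv")
  if (!is.null(res$abundance_scan)) wt(res$abundance_scan, "abundance_scan.tsv")
  if (!is.null(res$da)) wt(res$da, "da_neighbourhoods.tsv")
  if (!is.null(res$grouping))
    wt(data.frame(sample = names(groupingPartition(res$grouping)),
                  group = as.character(groupingPartition(res$grouping))),
       "sample_groups.tsv")
  lines <- c("# Pipeline summary", "",
             sprintf("- seed: %d", res$config$seed),
             sprintf("- stages: %s", paste(res$config$stages, collapse = ", ")))
  if (!is.null(res$qc))
    lines <- c(lines, sprintf("- QC: %d -> %d cells",
                              res$qc$n_barcodes_in, res$qc$n_barcodes_out))
  if (!is.null(res$clusters))
    lines <- c(lines, sprintf("- clusters: %d",
                              length(unique(res$clusters))))
  if (!is.null(res$grouping))
    lines <- c(lines, sprintf("- grouping empirical p: %.4g",
                              empiricalP(res$grouping)))
  if (!is.null(res$abundance_univariate))
    lines <- c(lines, sprintf(
      "- driver~abundance coefficient: %.4g (p = %.3g)",
      res$abundance_univariate$coefficient, res$abundance_univariate$p))
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(NULL)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult with stages:",
      paste(intersect(names(x), c("qc", "clusters", "pan_network", "markers",
                                  "grouping", "intra_network", "preservation",
                                  "variability", "abundance_scan", "da")),
            collapse = ", "), "\n")
  invisible(x)
}
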