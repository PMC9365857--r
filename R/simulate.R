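#' Configuration for a synthetic multi-sample scRNA-seq cohort
#'
#' Describes a cohort with planted transcriptional clusters, one rare cluster
#' carrying a driver-responsive target-gene module, and per-sample driver
#' activity that (i) scales target-module means inside the rare cluster and
#' (ii) tilts the rare cluster's per-sample abundance on the log-odds scale.
#'
#' Defaults emulate an eleven-individual colonic-epithelium cohort with a
#' rare (~1.5%) tuft-like cluster: 11 samples, 1,500 genes, 12 clusters,
#' ~455 cells per sample (~5,000 cells), a 60-gene target module, module
#' effect 4 (fold per unit driver activity), abundance coupling 1.
#'
#' @param n_samples number of samples (individuals).
#' @param n_genes total number of genes, including mitochondrial genes, the
#'   driver and the target module.
#' @param n_clusters number of transcriptional clusters.
#' @param rare_cluster_index 1-based index of the rare cluster.
#' @param base_abundance per-cluster baseline abundance; must sum to 1. If
#'   \code{NULL}, the rare cluster gets \code{rare_abundance} and the rest is
#'   split evenly.
#' @param rare_abundance baseline abundance of the rare cluster (<= 0.05).
#' @param cells_per_sample mean cells per sample; realised counts are
#'   negative binomial with size \code{cells_dispersion}.
#' @param cells_dispersion NB size parameter for cells per sample.
#' @param n_module size of the planted target module.
#' @param n_mito number of mitochondrial ("MT-") genes.
#' @param markers_per_cluster marker genes planted per non-rare cluster.
#' @param marker_fold expression fold of a cluster's markers inside it.
#' @param module_fold_rare fold of target-module genes in the rare cluster.
#' @param module_fold_other fold of target-module genes elsewhere.
#' @param driver_fold_rare,driver_fold_other cluster folds of the driver gene.
#' @param module_effect multiplicative fold applied to target-module means in
#'   the rare cluster per unit of (standard normal) driver activity.
#' @param abundance_coupling slope of the rare cluster's log-odds abundance
#'   on driver activity.
#' @param nb_dispersion per-gene NB dispersion phi (variance = m + phi m^2).
#' @param libsize_sigma lognormal sd of the per-cell library scaling.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(n_samples = 11L, n_genes = 1500L, n_clusters = 12L,
                      rare_cluster_index = 12L, base_abundance = NULL,
                      rare_abundance = 0.015, cells_per_sample = 455,
                      cells_dispersion = 50, n_module = 60L, n_mito = 10L,
                      markers_per_cluster = 30L, marker_fold = 8,
                      module_fold_rare = 15, module_fold_other = 0.15,
                      driver_fold_rare = 5, driver_fold_other = 0.5,
                      module_effect = 4, abundance_coupling = 1,
                      nb_dispersion = 0.4, libsize_sigma = 0.3, seed = 1L) {
  if (n_samples < 1 || n_genes < 1 || n_clusters < 1 || cells_per_sample < 1)
    stop("non-positive dimensions in simulation config")
  if (rare_cluster_index < 1 || rare_cluster_index > n_clusters)
    stop("rare_cluster_index out of range")
  if (is.null(base_abundance)) {
    base_abundance <- rep((1 - rare_abundance) / (n_clusters - 1), n_clusters)
    if (n_clusters == 1L) base_abundance <- 1
    base_abundance[rare_cluster_index] <- if (n_clusters == 1L) 1 else rare_abundance
  }
  if (length(base_abundance) != n_clusters)
    stop("base_abundance must have one entry per cluster")
  if (any(base_abundance <= 0) || any(base_abundance >= 1 + 1e-9))
    stop("base_abundance entries must lie in (0,1)")
  if (abs(sum(base_abundance) - 1) > 1e-9)
    stop("base_abundance must sum to 1")
  if (n_clusters > 1L && base_abundance[rare_cluster_index] > 0.05)
    stop("rare cluster base abundance must be <= 0.05")
  if (n_genes < n_mito + 1L + n_module)
    stop("n_genes too small for mito + driver + module genes")
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    rare_cluster_index = as.integer(rare_cluster_index),
    base_abundance = base_abundance, cells_per_sample = cells_per_sample,
    cells_dispersion = cells_dispersion, n_module = as.integer(n_module),
    n_mito = as.integer(n_mito),
    markers_per_cluster = as.integer(markers_per_cluster),
    marker_fold = marker_fold, module_fold_rare = module_fold_rare,
    module_fold_other = module_fold_other,
    driver_fold_rare = driver_fold_rare,
    driver_fold_other = driver_fold_other,
    module_effect = module_effect, abundance_coupling = abundance_coupling,
    nb_dispersion = nb_dispersion, libsize_sigma = libsize_sigma,
    seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_samples, "samples,", x$n_genes, "genes,",
      x$n_clusters, "clusters (rare =", x$rare_cluster_index, "at",
      signif(x$base_abundance[x$rare_cluster_index], 3), ")\n")
  cat("  module:", x$n_module, "genes, effect", x$module_effect,
      "; abundance coupling", x$abundance_coupling, "; seed", x$seed, "\n")
  invisible(x)
}

# NB draw parameterised by mean and dispersion phi (variance = mu + phi mu^2)
.rnbMu <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  rnbinom(n, size = 1 / phi, mu = mu)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-sample driver activity from a standard normal, assigns cells to
#' clusters with the rare cluster's probability tilted by
#' \code{plogis(qlogis(base) + coupling * activity)} (the remaining mass is
#' redistributed proportionally), and draws UMI counts as negative binomials
#' with mean \code{baseline_g * cluster_fold_gc * driver_scaling * libsize_i}.
#' Target-module genes are scaled by \code{module_effect^activity} inside the
#' rare cluster only; the driver gene's mean is proportional to
#' \code{exp(activity)} everywhere, making its observable expression a noisy
#' proxy of the latent activity.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return a \linkS4class{SingleCellExperiment} with a sparse \code{counts}
#'   assay, per-cell \code{sample} and \code{cluster_true} annotations,
#'   per-gene role annotations in \code{rowData}, and the ground truth
#'   (\code{metadata(x)$truth}: per-sample driver activity, expected and
#'   realised rare-cluster abundance, module membership) plus the config in
#'   \code{metadata(x)}.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  K <- config$n_clusters
  G <- config$n_genes
  S <- config$n_samples
  rare <- config$rare_cluster_index

  ## gene roles and names
  geneType <- rep("noise", G)
  idx <- seq_len(G)
  mito <- head(idx, config$n_mito)
  driver <- config$n_mito + 1L
  module <- seq(driver + 1L, driver + config$n_module)
  geneType[mito] <- "mito"; geneType[driver] <- "driver"
  geneType[module] <- "module"
  genes <- sprintf("G%04d", idx)
  genes[mito] <- sprintf("MT-%d", seq_along(mito))
  genes[driver] <- "DRV1"
  genes[module] <- sprintf("MOD%03d", seq_along(module))

  ## baselines (mean counts per gene per cell at libsize 1)
  baseline <- rlnorm(G, meanlog = log(0.3), sdlog = 0.7)
  baseline[mito] <- 3
  baseline[driver] <- 0.5
  baseline[module] <- 0.5

  ## cluster fold-change matrix (genes x clusters)
  fold <- matrix(1, G, K)
  pool <- setdiff(idx, c(mito, driver, module))
  markerSets <- vector("list", K)
  avail <- pool
  for (c in setdiff(seq_len(K), rare)) {
    take <- head(avail, config$markers_per_cluster)
    avail <- setdiff(avail, take)
    markerSets[[c]] <- take
    fold[take, c] <- config$marker_fold
  }
  fold[module, ] <- config$module_fold_other
  fold[module, rare] <- config$module_fold_rare
  fold[driver, ] <- config$driver_fold_other
  fold[driver, rare] <- config$driver_fold_rare

  ## sample-level latent activity and cluster probabilities
  activity <- rnorm(S)
  probs <- matrix(NA_real_, S, K)
  base <- config$base_abundance
  if (K > 1L) {
    pRare <- plogis(qlogis(base[rare]) + config$abundance_coupling * activity)
    for (s in seq_len(S)) {
      p <- base * (1 - pRare[s]) / (1 - base[rare])
      p[rare] <- pRare[s]
      probs[s, ] <- p
    }
  } else {
    pRare <- rep(1, S)
    probs[, 1] <- 1
  }

  nCells <- pmax(1L, .rnbMu(S, config$cells_per_sample,
                            1 / config$cells_dispersion))
  blocks <- vector("list", S)
  cellSample <- integer(0); cellCluster <- integer(0); cellLib <- numeric(0)
  for (s in seq_len(S)) {
    n <- nCells[s]
    cl <- sample.int(K, n, replace = TRUE, prob = probs[s, ])
    lib <- rlnorm(n, meanlog = 0, sdlog = config$libsize_sigma)
    mu <- baseline * fold[, cl, drop = FALSE]
    if (length(module))
      mu[module, cl == rare] <- mu[module, cl == rare] *
        config$module_effect^activity[s]
    mu[driver, ] <- mu[driver, ] * exp(activity[s])
    mu <- sweep(mu, 2L, lib, `*`)
    cnt <- matrix(.rnbMu(length(mu), as.vector(mu), config$nb_dispersion),
                  nrow = G)
    blocks[[s]] <- methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                           "CsparseMatrix"), "dMatrix")
    cellSample <- c(cellSample, rep.int(s, n))
    cellCluster <- c(cellCluster, cl)
    cellLib <- c(cellLib, lib)
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))

  sampleIds <- sprintf("S%02d", seq_len(S))
  realised <- vapply(seq_len(S), function(s)
    mean(cellCluster[cellSample == s] == rare), numeric(1))
  truth <- list(
    cell_cluster = cellCluster,
    sample_driver_activity = setNames(activity, sampleIds),
    module_members = genes[module],
    driver_gene = genes[driver],
    per_sample_rare_abundance = setNames(pRare, sampleIds),
    realised_rare_abundance = setNames(realised, sampleIds),
    cluster_probs = probs,
    marker_sets = lapply(markerSets, function(i) genes[i]))

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      sample = factor(sampleIds[cellSample], levels = sampleIds),
      cluster_true = cellCluster,
      libsize_factor = cellLib,
      row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(gene_type = geneType, row.names = genes),
    metadata = list(truth = truth, config = config))
}
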