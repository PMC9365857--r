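#' Group samples by hub-gene expression
#'
#' Complete-linkage hierarchical clustering of samples on Euclidean distance
#' over hub-gene z-scores, cut at the root into two branches; the branch
#' with the lower mean hub expression is labelled \code{"low"}.
#'
#' @param zscore genes-by-samples standardised pseudo-bulk expression.
#' @param hub_genes gene ids to cluster on.
#' @return factor (levels \code{high}, \code{low}) named by sample.
#' @export
groupSamplesByHubGenes <- function(zscore, hub_genes) {
  z <- as.matrix(zscore)[hub_genes, , drop = FALSE]
  d <- dist(t(z))
  if (max(d) <= 0) stop("degenerate dendrogram: all samples identical")
  hc <- hclust(d, method = "complete")
  grp <- cutree(hc, k = 2)
  means <- tapply(colMeans(z), grp, mean)
  lowId <- names(which.min(means))
  part <- factor(ifelse(grp == as.integer(lowId), "low", "high"),
                 levels = c("high", "low"))
  names(part) <- colnames(z)
  part
}

#' Empirical permutation p-value under the count/total convention
#'
#' @param n_matches number of permutations reproducing the observed result.
#' @param n_perm total number of permutations.
#' @return \code{n_matches / n_perm}.
#' @export
empiricalPValue <- function(n_matches, n_perm) {
  stopifnot(n_perm > 0, n_matches >= 0, n_matches <= n_perm)
  n_matches / n_perm
}

# do two 2-group labelings define the same unordered sample bipartition?
.samePartition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  all(a == b) || all(a == 3L - b)
}

#' Permutation null for a hub-gene sample grouping
#'
#' Draws \code{n_genes} genes uniformly without replacement \code{n_perm}
#' times, re-clusters the samples (complete linkage, root cut) on each draw,
#' and counts how often the observed unordered bipartition is reproduced
#' exactly. The empirical p-value is \code{matches / n_perm}.
#'
#' @param zscore genes-by-samples standardised pseudo-bulk expression.
#' @param observed factor of observed group labels (from
#'   \code{\link{groupSamplesByHubGenes}}).
#' @param n_genes genes per draw.
#' @param n_perm number of draws.
#' @param seed RNG seed.
#' @return a \linkS4class{SampleGrouping}.
#' @export
groupingPermutationP <- function(zscore, observed, n_genes = 10L,
                                 n_perm = 10000L, seed = 1L) {
  z <- as.matrix(zscore)
  if (n_genes > nrow(z)) stop("n_genes exceeds the gene count")
  set.seed(seed)
  obs <- as.integer(factor(observed))
  matches <- 0L
  for (i in seq_len(n_perm)) {
    gi <- sample.int(nrow(z), n_genes)
    d <- dist(t(z[gi, , drop = FALSE]))
    if (max(d) <= 0) next
    grp <- cutree(hclust(d, method = "complete"), k = 2)
    if (.samePartition(grp, obs)) matches <- matches + 1L
  }
  methods::new("SampleGrouping", partition = observed,
               nMatches = matches, nPerm = as.integer(n_perm),
               empiricalP = empiricalPValue(matches, n_perm))
}

#' Define the auxiliary module of driver-correlated target genes
#'
#' Target genes whose gene significance for the driver exceeds
#' \code{gs_min} with p-value below \code{gs_p_max}, and whose module
#' membership in the designated module exceeds \code{mm_min}.
#'
#' @param stats per-gene statistics from \code{\link{geneStatistics}} of the
#'   intra-cluster network.
#' @param target_genes candidate trans-eQTL target gene ids.
#' @param module module label the membership is assessed in (default: the
#'   module of each gene, i.e. only genes assigned to a module qualify).
#' @param gs_min,gs_p_max,mm_min thresholds.
#' @return character vector of auxiliary-module gene ids.
#' @export
defineAuxiliaryModule <- function(stats, target_genes, module = NULL,
                                  gs_min = 0.5, gs_p_max = 0.05,
                                  mm_min = 0.5) {
  s <- stats[stats$gene %in% target_genes, , drop = FALSE]
  if (!is.null(module)) s <- s[s$module %in% module, , drop = FALSE]
  else s <- s[s$module != "grey", , drop = FALSE]
  ok <- !is.na(s$GS) & s$GS > gs_min & s$GS_p < gs_p_max &
    !is.na(s$MM) & s$MM > mm_min
  s$gene[ok]
}

# kME of each gene in `genes` against the eigengene of that same set,
# within one cluster's standardised pseudo-bulk
.auxKME <- function(zscore, genes) {
  z <- as.matrix(zscore)[genes, , drop = FALSE]
  eg <- .firstEigengene(z)
  as.vector(cor(t(z), eg))
}

#' Cross-cluster preservation of an auxiliary module (cor.kME)
#'
#' In the reference cluster and in each test cluster, computes the kME of
#' every auxiliary gene against the auxiliary-module eigengene of that
#' cluster; \code{cor_kme} is the Pearson correlation between the test and
#' reference kME vectors (1 for the reference against itself), with a
#' Student-t p-value, and \code{average_mm} is the mean kME per cluster.
#' Clusters in which fewer than 2 auxiliary genes are measurable are
#' excluded.
#'
#' @param pb_by_cluster named list of genes-by-samples z-scored pseudo-bulk
#'   matrices, one per cluster.
#' @param reference name of the reference cluster in \code{pb_by_cluster}.
#' @param aux_genes auxiliary module gene ids.
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{n_genes}, \code{cor_kme}, \code{cor_kme_p}, \code{average_mm}.
#' @export
preservationCorKME <- function(pb_by_cluster, reference, aux_genes) {
  stopifnot(reference %in% names(pb_by_cluster))
  usable <- function(z) {
    g <- intersect(aux_genes, rownames(z))
    g[matrixStats::rowSds(as.matrix(z)[g, , drop = FALSE]) > 0]
  }
  refGenes <- usable(pb_by_cluster[[reference]])
  if (length(refGenes) < 2L)
    stop("fewer than 2 auxiliary genes measurable in the reference cluster")
  refKME <- setNames(.auxKME(pb_by_cluster[[reference]], refGenes), refGenes)
  rows <- lapply(names(pb_by_cluster), function(cl) {
    g <- intersect(usable(pb_by_cluster[[cl]]), refGenes)
    if (length(g) < 2L) return(NULL)
    kme <- setNames(.auxKME(pb_by_cluster[[cl]], g), g)
    r <- if (cl == reference) 1 else as.numeric(cor(kme, refKME[g]))
    data.frame(cluster = cl, n_genes = length(g), cor_kme = r,
               cor_kme_p = corPValue(r, length(g)), average_mm = mean(kme))
  })
  do.call(rbind, rows)
}

#' Pairwise correlation panels of auxiliary genes across clusters
#'
#' For each cluster, the Pearson correlation matrix of the auxiliary genes
#' (plus the driver) over samples, with entries at p >= \code{alpha} masked
#' to \code{NA}; clusters with no significant off-diagonal entry are
#' flagged.
#'
#' @param pb_by_cluster named list of genes-by-samples pseudo-bulk matrices.
#' @param genes auxiliary gene ids (include the driver to reproduce the
#'   published panels).
#' @param alpha significance mask level.
#' @return list with \code{panels} (named list of masked correlation
#'   matrices) and \code{no_signif} (cluster names without any significant
#'   pair).
#' @export
pairwiseCorrelationPanel <- function(pb_by_cluster, genes, alpha = 0.05) {
  panels <- lapply(pb_by_cluster, function(z) {
    g <- intersect(genes, rownames(z))
    m <- as.matrix(z)[g, , drop = FALSE]
    cc <- suppressWarnings(cor(t(m)))
    p <- corPValue(cc, ncol(m))
    cc[p >= alpha | is.na(p)] <- NA_real_
    diag(cc) <- 1
    cc
  })
  noSig <- names(panels)[vapply(panels, function(cc)
    all(is.na(cc[upper.tri(cc)])), TRUE)]
  list(panels = panels, no_signif = noSig)
}

#' Per-cluster variability of selected genes
#'
#' Pseudo-bulks each cluster independently (sample-within-cluster units),
#' z-scores genes across all units so variability is comparable between
#' clusters, and reports per gene and cluster: the variance of the
#' per-sample z-scores, the raw single-cell variance, and the
#' variance-stabilised standardised single-cell variance. The cluster
#' maximising each measure is reported per gene.
#'
#' @param counts genes-by-cells count matrix.
#' @param sample,cluster per-cell labels.
#' @param genes genes to report (default all).
#' @return list with \code{table} (long data.frame) and \code{argmax}
#'   (per-gene data.frame of the maximising cluster under each measure).
#' @export
perClusterVariability <- function(counts, sample, cluster, genes = NULL) {
  m <- .asCountMatrix(counts)
  if (is.null(genes)) genes <- rownames(m)
  pb <- pseudobulk(m, by = "sample_cluster", sample = sample,
                   cluster = cluster)
  z <- SummarizedExperiment::assay(pb, "zscore")
  unitCl <- SummarizedExperiment::colData(pb)$cluster
  cls <- sort(unique(as.character(cluster)))
  rows <- list()
  for (cl in cls) {
    zc <- z[genes, unitCl == cl, drop = FALSE]
    pbVar <- matrixStats::rowVars(zc)
    cells <- m[genes, as.character(cluster) == cl, drop = FALSE]
    st <- vstStats(cells)
    rows[[cl]] <- data.frame(gene = genes, cluster = cl,
                             pb_zscore_var = pbVar,
                             sc_raw_var = st$variance,
                             sc_std_var = st$variance_standardized,
                             row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  am <- function(col) {
    w <- tapply(tab[[col]], tab$gene, function(v) cls[which.max(v)])
    w[genes]
  }
  argmax <- data.frame(gene = genes,
                       pb_zscore_var = am("pb_zscore_var"),
                       sc_raw_var = am("sc_raw_var"),
                       sc_std_var = am("sc_std_var"), row.names = NULL)
  list(table = tab, argmax = argmax)
}

#' Cross-dataset variance fold-change permutation test
#'
#' For each shared target gene, the fold change of normalised single-cell
#' variance between two datasets (A over B); the observed mean fold change
#' over targets is compared with a null built from \code{n_perm} random
#' same-size gene sets drawn from the shared expressed universe
#' (p with +1 smoothing), and a percentile bootstrap over target genes gives
#' a 95% confidence interval for the mean.
#'
#' @param norm_var_A,norm_var_B named per-gene normalised variances.
#' @param target_genes target gene ids.
#' @param n_perm null gene-set draws.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed RNG seed.
#' @return list with \code{fc} (per-gene fold changes), \code{median},
#'   \code{mean}, \code{ci95}, \code{p}, \code{n_targets}.
#' @export
varianceFoldChangeTest <- function(norm_var_A, norm_var_B, target_genes,
                                   n_perm = 100000L, n_boot = 10000L,
                                   seed = 1L) {
  shared <- intersect(names(norm_var_A), names(norm_var_B))
  ok <- shared[norm_var_B[shared] > 0 & is.finite(norm_var_A[shared])]
  fcAll <- norm_var_A[ok] / norm_var_B[ok]
  targets <- intersect(target_genes, ok)
  dropped <- setdiff(intersect(target_genes, shared), targets)
  if (length(dropped))
    warning("dropped targets with zero denominator variance: ",
            paste(dropped, collapse = ", "))
  if (length(targets) == 0L) stop("no usable target genes")
  fc <- fcAll[targets]
  obs <- mean(fc)
  set.seed(seed)
  nt <- length(targets)
  nullMeans <- vapply(seq_len(n_perm), function(i)
    mean(fcAll[sample.int(length(fcAll), nt)]), numeric(1))
  p <- (1 + sum(nullMeans >= obs)) / (1 + n_perm)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(fc[sample.int(nt, nt, replace = TRUE)]), numeric(1))
  list(fc = fc, median = median(fc), mean = obs,
       ci95 = unname(quantile(boot, c(0.025, 0.975))), p = p,
       n_targets = nt)
}
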