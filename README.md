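# scModuleMap

Tools for asking whether a set of trans-eQTL target genes forms a
co-expression network that is specific to a **rare transcriptional cell
cluster** in multi-sample single-cell RNA-seq — the in-silico situation in
which a locus regulates a couple of dozen distant genes whose coherence is
confined to a cell type making up ~1% of the tissue (in the motivating
setting: a POU2AF2-like cis-regulated driver, its trans targets, and
colonic tuft cells).

The package chains, behind one orchestrator and as individually exported
stages:

* droplet/cell/gene QC (barcode-rank inflection, ≥ 20-cell gene filter,
  sparsity > 0.99 cell filter, mitochondrial median + 2.5 MAD filter);
* per-sample pseudo-bulk aggregation with TMM normalisation
  (log2 CPM, per-gene z-scores);
* a signed weighted co-expression network: soft power by scale-free fit,
  adjacency ((1 + r)/2)^β, topological overlap
  TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij),
  average-linkage dynamic tree cut with eigengene merging and a
  core-anchored kME refinement, module eigengenes (first singular
  vectors), module–trait Pearson/Student-t/BH statistics, and hub genes
  (MM > 0.7, kIM > 0.7, adjacency > 0.3);
* graph-based clustering (vst variable genes, PCA, Jaccard SNN, Louvain at
  resolution 0.6) with a marker-AUC cluster-merge rule;
* two-part hurdle marker tests (binomial detection LRT + Gaussian LRT,
  χ² 2 df) with the published record arithmetic (expm1-scale log2FC,
  pct.1/pct.2, Bonferroni min(1, p·G));
* preranked GSEA with a seeded gene-set-sampling null;
* hub-gene sample grouping (complete linkage, root cut) with an exact
  bipartition permutation null (empirical p = matches/draws);
* auxiliary-module preservation across clusters (cor.kME with Student-t
  p, average MM) and pairwise correlation panels;
* abundance modelling: OLS of abundance on driver expression, a
  genome-wide moderated scan (empirical-Bayes shrinkage, BH), and
  kNN-neighbourhood differential abundance (NB GLM with TMM offsets,
  distance-weighted spatial FDR, majority-cluster > 0.8 filtering);
* a negative-binomial cohort simulator with planted clusters, a
  driver-responsive target module and driver-coupled rare-cluster
  abundance, providing ground truth for every stage.

## Worked example

```r
library(scModuleMap)

sce <- generateCohort(simConfig(seed = 1))   # 11 samples, ~5,000 cells,
                                             # 1,500 genes, 60-gene module,
                                             # 1.5% rare cluster
res <- runPipeline(sce, pipelineConfig(seed = 1))

length(unique(res$clusters))        # 12   (planted: 12; ARI 1.0 vs truth)
res$rare_candidate                  # 11   (the 134-cell tuft-like cluster)
head(res$markers, 3)
#>     gene      p_val avg_log2FC  pct.1   pct.2  p_val_adj
#>   MOD028 1.363e-297      5.782 0.9851 0.07624 2.045e-294
#>   MOD040 4.616e-295      5.731 0.9627 0.08556 6.923e-292
#>   MOD031 8.853e-288      5.731 1.0000 0.07285 1.328e-284
res$marker_enrichment$p             # 0.00017 — planted targets enriched in
                                    # the candidate's marker ranking
length(res$hub_genes)               # 61 hub genes of the driver module
empiricalP(res$grouping)            # 0.007 — 10-gene permutation null of
                                    # the high/low sample split
res$abundance_univariate$coefficient  # 0.0116 (p = 1.3e-4): driver
                                    # expression predicts rare abundance
subset(res$da_filtered, majority_cluster == "11")$logFC < 0
#> all TRUE — every rare-cluster neighbourhood is depleted (spatial
#> FDR < 0.01) in the low-expression sample group
```

The top markers, the hub genes and the abundance-scan hits are all planted
module genes, and the preservation table (`res$preservation`) puts
cor.kME = 1 in the rare cluster with near-zero values elsewhere — the
pipeline recovers the full chain of claims from the ground truth.

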