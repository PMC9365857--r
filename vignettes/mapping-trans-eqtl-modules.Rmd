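---
title: "Mapping trans-eQTL target modules to rare cell clusters"
author: "scModuleMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-eQTL target modules to rare cell clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scModuleMap)
```

## The scientific question

A locus can regulate a set of distant genes (trans-eQTL targets) whose
co-expression is invisible in bulk tissue if it is confined to a rare cell
type. The motivating setting is colonic epithelium: a cis-regulated driver
gene (a POU2AF2-like transcriptional cofactor) and a couple of dozen
trans-eQTL targets, several of which are known tuft-cell markers — a
chemosensory cell type making up roughly 1% of the epithelium. The package
asks, for multi-sample scRNA-seq: do the targets form a coherent
co-expression module; is that module tied to the driver; is the module's
expression, variability and gene–gene connectivity specific to one rare
cluster; and does target expression predict that cluster's abundance?

The workflow chains: droplet/cell/gene QC, per-sample pseudo-bulk with TMM
normalisation, a signed weighted co-expression network over samples,
graph-based cell clustering with a marker-AUC merge rule, hurdle marker
tests, preranked gene set enrichment, hub-gene sample grouping with a
permutation null, intra-cluster network plus auxiliary-module preservation
(cor.kME), per-cluster variability tables, and abundance modelling (a
moderated per-gene scan and kNN-neighbourhood differential abundance).

## A minimal run

```{r, eval = FALSE}
sce <- generateCohort(simConfig(seed = 1))
res <- runPipeline(sce, pipelineConfig(seed = 1), verbose = TRUE)
res$markers[1:5, ]
empiricalP(res$grouping)
res$preservation
```

## The models, stage by stage

**QC.** Empty droplets are removed at the inflection of the barcode-rank
curve: the steepest negative slope of a 3-point moving-average smoothed
log10(count) vs log10(rank) curve, with the threshold placed at the
geometric midpoint of the flanking smoothed counts. Genes expressed in
fewer than 20 cells are dropped; cells with expression sparsity above 0.99
are dropped (strict inequality); cells whose mitochondrial proportion
exceeds median + 2.5 MAD are dropped. The MAD is deliberately unscaled (no
1.4826 factor) and the cut is one-sided: high mitochondrial content is the
damaged-cell signature, and a symmetric cut would discard healthy cells
with unusually low mitochondrial load. The mito filter recomputes its
robust statistics from its input, so it is idempotent whenever removing
the outlier tail leaves median and MAD unchanged (the damaged-cell
scenario) but not on arbitrary continuous data; the single-pass behaviour
is intentional.

**Pseudo-bulk.** Counts are summed per sample (or per sample-within-
cluster), normalised by TMM-effective library sizes (edgeR's trimmed mean
of M-values: 30% M-trim, 5% A-trim, precision weights, reference by upper
quartile), log2-transformed as CPM with a 0.5 pseudocount, and z-scored per
gene with the sample (n-1) standard deviation. The two normalisation
phrasings in circulation ("z-scored across genes" vs "across samples") are
reconciled as: standardise each gene over its units — the only reading
under which gene–gene correlation analysis is meaningful.

**Co-expression network.** Pearson correlation over units; signed
adjacency \((1 + r)/2)^\beta\); topological overlap
\(TOM_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})\);
average-linkage clustering of \(1 - TOM\). The soft power is the smallest
one whose connectivity distribution fits scale-free topology at signed
R² ≥ 0.85 (10 log-log bins), falling back to the best-fitting power.
Modules come from a recursive dendrogram branch cut (branches of ≥ 30
leaves, local cut at 0.99 × the branch's top merge height), merged when
their eigengene dissimilarity falls below 0.25, where a module eigengene is
the first right-singular vector of the row-standardised module submatrix,
sign-oriented along the module's average expression.

With only ~11 pseudo-bulk samples, chance gene–gene correlations are large
(null sd ≈ 0.32), and under average linkage a few hundred unrelated genes
chain onto any genuine module branch. The tree cut is therefore followed by
a *core-anchored kME refinement*: each module's eigengene is recomputed
from its 30 most intramodularly connected genes, and a gene is retained
only if its correlation with that core eigengene is significantly positive
(one-sided p < 0.005, Student t with n−2 df). The level is chosen so that
the expected number of chance survivors (p × n genes ≈ 7 of 1,500) stays
well below the minimum module size; genes of a genuine tight module sit
far above the critical correlation and are not at risk. Refinement is skipped below 6 samples, where the
critical correlation approaches 1. This stage replaces the PAM stage of
the hybrid tree-cut algorithm, which remains deliberately omitted.

The intra-cluster network (soft power 6 by default, up to the 5,000 most
variable genes) does *not* apply the refinement: its module is expected to
be broad, and the auxiliary-module selection applies its own GS/MM filter
(GS > 0.5 with p < 0.05, MM > 0.5) downstream.

**Clustering.** Variable genes are ranked by variance-stabilised
standardised variance (loess fit of log10 variance on log10 mean,
clipping at √n cells; ties broken by gene id). PCA uses the
eigendecomposition of the smaller-dimension covariance with component
signs fixed by the largest-magnitude loading. The SNN graph weighs cell
pairs by the Jaccard overlap of their (self-inclusive) k-NN sets, and
Louvain maximises modularity at resolution 0.6. Cluster pairs separated by
fewer than 30 genes at two-sided AUC ≥ 0.6 are merged, closest pair first,
until stable. The default k scales as clamp(n cells / 50, 20, 250): the
published k = 250 at ~32,000 cells corresponds to ~0.8 of the rare
cluster's size, and keeping that ratio at smaller cohort sizes is what
lets a ~75-cell cluster survive graph smoothing; a fixed k = 250 at 5,000
cells would dissolve it.

**Markers.** Expression is ln(TP10K + 1). The marker test is a two-part
hurdle likelihood-ratio test: a binomial LRT on the detection rate plus a
Gaussian LRT on the positive values, combined as χ² with 2 df. This is a
deliberately self-contained approximation of the published hurdle
framework — marker p-values on real data will differ numerically from the
published table, while the record arithmetic (log2 fold change on the
expm1 scale, detection fractions, Bonferroni `min(1, p × G)`) matches it
exactly. All QC-passing genes are tested, with no detection or fold-change
pre-filter, matching the published Bonferroni multiplier.

**Enrichment.** Preranked GSEA with hit increments \(|s|^w\) (w = 1 by
default), miss decrements 1/(N − N\_hit), ES the extremum of the running
sum (the positive extremum wins exact ties), and a seeded gene-set-
sampling null (default 10,000 draws; the permutation count is not pinned
by the published analysis). NES divides by the mean magnitude of same-sign
null scores; p counts same-sign null scores at least as extreme, with +1
smoothing.

**Sample grouping.** Samples are complete-linkage clustered on Euclidean
distance over hub-gene z-scores (hubs: MM > 0.7, scaled kIM > 0.7, maximal
intramodular adjacency > 0.3) and split at the root; the group with lower
mean hub expression is "low". The permutation null redraws 10 random genes
10,000 times and counts exact unordered bipartition matches; the empirical
p is matches/draws — the convention pinned by the published 550/10,000 =
0.055. Note this statistic is a match *frequency*, not a rank-based
p-value: under a null cohort it concentrates near the cohort's intrinsic
match rate rather than being uniform.

**Preservation.** The auxiliary module (driver-correlated targets from the
intra-cluster network) is scored in every cluster by the correlation
between each gene's kME (against the cluster's own auxiliary eigengene)
and the reference cluster's kME vector; p from the Student-t transform;
mean kME reported. Clusters with fewer than 2 measurable auxiliary genes
are excluded. With a dozen auxiliary genes the per-cluster p-values of
null clusters are uniform, so when ~11 clusters are tested, one nominally
significant cluster appears in roughly 40% of cohorts by multiplicity
alone — a BH-adjusted column is also reported for multi-cluster claims.

**Abundance.** The single-gene direction regresses cluster abundance on
expression (plain OLS); the genome-wide direction regresses each gene's
log expression on abundance, with residual variances shrunk by
empirical-Bayes moment matching (limma's scaled inverse-chi-square fit)
and BH adjustment. Neighbourhoods are built in 4 PCs around refined index
cells (10% sampling, centroid refinement, deduplication; default k =
clamp(n cells / 100, 20, 250), the same size-ratio argument as above);
counts per sample are tested by a negative-binomial GLM with a
TMM-effective offset and a common moment-estimated dispersion, using a
likelihood-ratio χ² — a self-contained approximation of a quasi-likelihood
F-test, calibrated on simulation (type-I error within 1.5× nominal at
α = 0.05). The spatial FDR is Benjamini-Hochberg weighted by reciprocal
kth-neighbour distance; plain BH is available by flag. Neighbourhoods are
annotated with their majority cluster and filtered at proportion > 0.8.

## The synthetic cohort

`simConfig()`/`generateCohort()` emulate the study conditions: 11 samples,
1,500 genes, 12 clusters of which one ("tuft-like") has baseline abundance
1.5%, ~455 cells per sample (~5,000 cells), a 60-gene target module, and a
latent per-sample driver activity drawn from a standard normal that (i)
multiplies target-module means inside the rare cluster by
`module_effect^activity` (default 4) and (ii) tilts the rare cluster's
per-cell log-odds abundance with slope 1, the remaining probability mass
being redistributed proportionally. The driver gene's own mean is
proportional to `exp(activity)` everywhere — its observable expression is
a noisy proxy of the latent activity, mimicking genotype-driven expression
variation without simulating genotypes. Counts are negative binomial
(dispersion 0.4, variance m + φm²) with per-cell lognormal library scaling
(sd 0.3, emulating depth variation); each non-rare cluster carries 30
planted marker genes at 8-fold enrichment; module genes are 15-fold
enriched in the rare cluster and depleted (0.15×) elsewhere; ten "MT-"
genes carry high baselines so the mitochondrial filter is exercised.

What the generator does *not* emulate: batch effects and their
integration, doublets, ambient RNA, UMI saturation, cell-cycle structure,
and continuous differentiation trajectories. Passing tests therefore show
that the pipeline recovers a planted, cleanly separated rare-cluster
module under realistic count noise and depth variation — not that it is
robust to batch confounding or to biology that blurs cluster boundaries.

## Numerical choices and degenerate inputs

* z-scores use the sample (n−1) sd; the log offset is a 0.5-CPM
  pseudocount; both are unstated in the source analysis and fixed here.
* Zero-variance genes are flagged and z-scored to zero; constant genes are
  dropped from the abundance scan with a warning; zero-variance
  denominators are dropped from the variance fold-change test with a
  warning.
* The hurdle test guards its Gaussian part against floating-point
  cancellation: sums of squares below 1e-10 of their magnitude are treated
  as zero (constant positives), contributing no statistic.
* The AUC merge rule uses midranks; the ≥ 0.6 cut is two-sided
  (max(AUC, 1−AUC)), since the published phrasing does not state
  sidedness.
* All-equal barcode counts raise "no inflection found"; identical samples
  raise "degenerate dendrogram"; a sample grouping with a single-sample
  group skips differential abundance with an explanatory record rather
  than failing the run.
* One user seed fans out deterministically per stage (`stageSeed`), so
  disabling one stage does not shift another's randomness; identical seed
  and config reproduce byte-identical tables.
* The pan-cluster network's gene universe is whatever matrix it is given;
  the pipeline default is all QC-passing genes z-scored after subsetting
  (subset-then-standardise).

## Problem sizes in the test-suite

The validation suite exercises the default cohort (11 × ~5,000 × 1,500,
60-gene module) across 20 seeds for module and cell-specificity recovery,
and smaller structured cohorts (8 samples, ~960 cells, 320 genes) for
unit-level properties; oracle checks (topological overlap, enrichment
walks, TMM trimming, OLS, AUC pair counting) run on 5–1,000-element
instances where brute force is exact. Null calibrations use 200–600
replicates at KS α = 0.01. These sizes were chosen so the full suite
completes comfortably on a single CPU while keeping every Monte-Carlo
margin wide.

## Known limitations

* Marker p-values approximate (not reproduce) the published hurdle
  framework's; only the record arithmetic is exact.
* The quasi-likelihood F-test for neighbourhood abundance is approximated
  by an NB LRT with common moment dispersion; with very few samples per
  group the F-test's small-sample protection is not replicated.
* Module preservation reports the extracted statistics (cor.kME, its p,
  average MM) only, not the full permutation-Z preservation suite.
* No batch integration: on real multi-batch data, clustering and networks
  should be run on integrated embeddings produced upstream.
* With ~10 samples, every correlation-based quantity carries wide
  sampling error; the refinement and significance conventions above are
  tuned to that regime and should be revisited for cohorts of 50+ samples.
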