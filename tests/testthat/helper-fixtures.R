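# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# a small but structured cohort: 8 samples, 6 clusters (rare = 6), 320 genes,
# ~120 cells/sample; fast enough for unit tests while keeping planted truth
smallConfig <- function(seed = 11L, ...) {
  simConfig(n_samples = 8L, n_genes = 320L, n_clusters = 6L,
            rare_cluster_index = 6L, rare_abundance = 0.04,
            cells_per_sample = 120, n_module = 25L, n_mito = 5L,
            markers_per_cluster = 15L, module_effect = 4,
            abundance_coupling = 1, seed = seed, ...)
}

smallCohort <- function() cached("smallCohort", generateCohort(smallConfig()))

# genes-by-samples z-scored matrix with two planted correlated blocks and
# noise genes; block structure driven by latent sample factors
blockZScore <- function(nBlock = c(50L, 50L), nNoise = 100L, nSamples = 12L,
                        noiseSD = 0.35, seed = 5L) {
  set.seed(seed)
  mats <- list()
  for (b in seq_along(nBlock)) {
    f <- rnorm(nSamples)
    mats[[b]] <- t(vapply(seq_len(nBlock[b]), function(i)
      f + rnorm(nSamples, sd = noiseSD), numeric(nSamples)))
  }
  noise <- matrix(rnorm(nNoise * nSamples), nNoise, nSamples)
  x <- rbind(do.call(rbind, mats), noise)
  rownames(x) <- c(sprintf("B%d_%03d", rep(seq_along(nBlock), nBlock),
                           unlist(lapply(nBlock, seq_len))),
                   sprintf("N%03d", seq_len(nNoise)))
  colnames(x) <- sprintf("S%02d", seq_len(nSamples))
  zscoreGenes(x)
}
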