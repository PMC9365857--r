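test_that("config validation rejects impossible cohorts", {
  expect_error(simConfig(n_samples = 0), "non-positive")
  expect_error(simConfig(rare_cluster_index = 20), "out of range")
  expect_error(simConfig(rare_abundance = 0.2), "<= 0.05")
  expect_error(simConfig(base_abundance = c(0.5, 0.5)), "one entry per cluster")
  bad <- rep(1 / 12, 12); bad[1] <- bad[1] + 0.01
  expect_error(simConfig(base_abundance = bad), "sum to 1")
})

test_that("identical seeds give bit-identical cohorts", {
  a <- generateCohort(smallConfig(seed = 3))
  b <- generateCohort(smallConfig(seed = 3))
  expect_identical(
    as.matrix(SummarizedExperiment::assay(a, "counts")),
    as.matrix(SummarizedExperiment::assay(b, "counts")))
  expect_identical(S4Vectors::metadata(a)$truth$sample_driver_activity,
                   S4Vectors::metadata(b)$truth$sample_driver_activity)
  d <- generateCohort(smallConfig(seed = 4))
  expect_false(identical(
    as.matrix(SummarizedExperiment::assay(a, "counts")),
    as.matrix(SummarizedExperiment::assay(d, "counts"))))
})

test_that("counts follow negative-binomial moments", {
  ## one flat cluster, no library-size variation: each gene's draws are iid
  ## NB with variance m + phi m^2
  phi <- 0.5
  cfg <- simConfig(n_samples = 1L, n_genes = 40L, n_clusters = 1L,
                   rare_cluster_index = 1L, rare_abundance = 0.01,
                   cells_per_sample = 50000, cells_dispersion = 1e9,
                   n_module = 2L, n_mito = 1L, markers_per_cluster = 0L,
                   module_effect = 1, abundance_coupling = 0,
                   nb_dispersion = phi, libsize_sigma = 0, seed = 42L)
  sce <- generateCohort(cfg)
  m <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  mu <- rowMeans(m)
  v <- matrixStats::rowVars(m)
  expected <- mu + phi * mu^2
  ## variance within 10% of NB moments for reasonably expressed genes
  ok <- mu > 0.2
  expect_gt(sum(ok), 10)
  expect_true(all(abs(v[ok] / expected[ok] - 1) < 0.10))
  ## mean within 3 SE of itself is trivial; instead check the mean is stable
  ## across two halves of the draws (same generating mean)
  h1 <- rowMeans(m[, 1:25000]); h2 <- rowMeans(m[, 25001:50000])
  se <- sqrt(expected / 25000)
  expect_true(all(abs(h1 - h2)[ok] < 6 * se[ok]))
})

test_that("zero coupling and unit module effect give a null cohort", {
  slopes <- vapply(1:20, function(s) {
    cfg <- simConfig(n_samples = 8L, n_genes = 120L, n_clusters = 3L,
                     rare_cluster_index = 3L, rare_abundance = 0.04,
                     cells_per_sample = 80, n_module = 15L, n_mito = 3L,
                     markers_per_cluster = 10L, module_effect = 1,
                     abundance_coupling = 0, seed = 100 + s)
    sce <- generateCohort(cfg)
    truth <- S4Vectors::metadata(sce)$truth
    m <- SummarizedExperiment::assay(sce, "counts")
    sm <- SummarizedExperiment::colData(sce)$sample
    pb <- aggregateCounts(m, sm)
    ## per-sample mean module expression relative to depth
    rel <- colMeans(pb[truth$module_members, ]) / colSums(pb)
    unname(coef(lm(rel ~ truth$sample_driver_activity))[2])
  }, numeric(1))
  ## slope distribution centred on zero
  tt <- t.test(slopes)
  expect_gt(tt$p.value, 0.01)
})

test_that("rare-cluster abundance increases with driver activity", {
  rhos <- vapply(1:20, function(s) {
    cfg <- simConfig(n_samples = 10L, n_genes = 60L, n_clusters = 4L,
                     rare_cluster_index = 4L, rare_abundance = 0.04,
                     cells_per_sample = 300, n_module = 5L, n_mito = 2L,
                     markers_per_cluster = 5L, abundance_coupling = 1,
                     seed = 200 + s)
    truth <- S4Vectors::metadata(generateCohort(cfg))$truth
    cor(truth$realised_rare_abundance, truth$sample_driver_activity,
        method = "spearman")
  }, numeric(1))
  expect_gte(sum(rhos > 0), 18)
  ## and the latent probabilities are exactly monotone in activity
  truth <- S4Vectors::metadata(smallCohort())$truth
  o <- order(truth$sample_driver_activity)
  expect_true(all(diff(truth$per_sample_rare_abundance[o]) > 0))
})

test_that("planted module genes correlate above background in pseudo-bulk", {
  sce <- smallCohort()
  truth <- S4Vectors::metadata(sce)$truth
  pb <- pseudobulk(sce)
  z <- SummarizedExperiment::assay(pb, "zscore")
  cc <- cor(t(z))
  inMod <- rownames(z) %in% truth$module_members
  modPairs <- cc[inMod, inMod][upper.tri(cc[inMod, inMod])]
  bgPairs <- cc[!inMod, !inMod][upper.tri(cc[!inMod, !inMod])]
  expect_gt(median(modPairs), median(bgPairs))
  expect_gt(median(modPairs), 0.5)
})

test_that("fixtures round-trip losslessly through MTX + TSV", {
  sce <- smallCohort()
  dir <- withr::local_tempdir()
  writeFixture(sce, dir)
  back <- readFixture(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_identical(rownames(back), rownames(sce))
  expect_identical(
    as.character(SummarizedExperiment::colData(back)$sample),
    as.character(SummarizedExperiment::colData(sce)$sample))
  tr <- S4Vectors::metadata(back)$truth
  expect_equal(tr$sample_driver_activity,
               S4Vectors::metadata(sce)$truth$sample_driver_activity,
               tolerance = 1e-12)
  expect_identical(tr$module_members,
                   S4Vectors::metadata(sce)$truth$module_members)
})

test_that("MTX body lists exactly the 1-based nonzeros; empty matrix valid", {
  m <- Matrix::sparseMatrix(i = c(1, 3, 3), j = c(1, 1, 2), x = c(5, 2, 7),
                            dims = c(3, 2))
  rownames(m) <- c("g1", "g2", "g3"); colnames(m) <- c("c1", "c2")
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  dir <- withr::local_tempdir()
  writeFixture(sce, dir)
  body <- readLines(file.path(dir, "matrix.mtx"))
  body <- body[!grepl("^%", body)]
  expect_identical(body[1], "3 2 3")
  trip <- do.call(rbind, lapply(strsplit(body[-1], " "), as.numeric))
  trip <- trip[order(trip[, 2], trip[, 1]), , drop = FALSE]
  expect_equal(trip, rbind(c(1, 1, 5), c(3, 1, 2), c(3, 2, 7)))
  ## degenerate: no nonzeros
  e <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(2, 2))
  rownames(e) <- c("g1", "g2"); colnames(e) <- c("c1", "c2")
  esce <- SingleCellExperiment::SingleCellExperiment(list(counts = e))
  writeFixture(esce, file.path(dir, "empty"))
  back <- readFixture(file.path(dir, "empty"))
  expect_equal(sum(SummarizedExperiment::assay(back, "counts")), 0)
  expect_identical(dim(back), dim(esce))
})
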