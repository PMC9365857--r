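test_that("signed adjacency follows its closed form", {
  cc <- matrix(c(1, 1, -1, 0,
                 1, 1, 0, 0.5,
                 -1, 0, 1, 0,
                 0, 0.5, 0, 1), 4, 4)
  a <- adjacencySigned(cc, 14)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.5^14)
  expect_equal(a[2, 4], 0.75^14)
  ## monotone decreasing in beta for cor < 1
  for (b in 1:10) expect_gt(adjacencySigned(cc, b)[1, 4],
                            adjacencySigned(cc, b + 1)[1, 4])
})

test_that("TOM collapses correctly on tiny networks", {
  ## 2 genes: TOM equals the adjacency entry
  for (x in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(1, x, x, 1), 2, 2)
    expect_equal(tomMatrix(a)[1, 2], x)
  }
  ## perfect triangle: overlap 1
  a3 <- matrix(1, 3, 3)
  expect_true(all(abs(tomMatrix(a3) - 1) < 1e-12))
  expect_error(tomMatrix(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("TOM equals the triple-loop oracle on random instances", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    cc <- cor(matrix(rnorm(n * 12), 12, n))
    a <- adjacencySigned(cc, sample(2:8, 1))
    expect_lt(max(abs(tomMatrix(a) - bruteTOM(a))), 1e-12)
  }
})

test_that("soft-threshold selection takes the first power meeting the fit cut", {
  ## heavy-tailed factor loadings give a graded connectivity spectrum whose
  ## signed fit improves monotonically with the power
  set.seed(44)
  n <- 12; G <- 200
  f <- rnorm(n)
  lam <- runif(G)^2 * 3
  x <- lam %o% f + matrix(rnorm(G * n), G, n)
  rownames(x) <- sprintf("g%03d", 1:G); colnames(x) <- sprintf("s%02d", 1:n)
  z <- zscoreGenes(x)
  ps <- pickSoftThreshold(z, powers = 1:12, rsq_cut = 0.4)
  expect_true(ps$reached)
  tab <- ps$fit_table
  expect_identical(ps$beta, tab$power[which(tab$signed_rsq >= 0.4)[1]])
  expect_gt(ps$beta, 1)
  ## independent noise never meets the default cut: fallback branch
  set.seed(13)
  zn <- zscoreGenes(matrix(rnorm(80 * 8), 80, 8,
                           dimnames = list(sprintf("g%d", 1:80),
                                           sprintf("s%d", 1:8))))
  psn <- pickSoftThreshold(zn, powers = 1:4)
  expect_false(psn$reached)
  expect_identical(psn$beta,
                   psn$fit_table$power[which.max(psn$fit_table$signed_rsq)])
  ## single-power candidate list returns it
  expect_identical(pickSoftThreshold(z, powers = 6)$beta, 6)
})

test_that("module detection recovers planted blocks and handles degenerate input", {
  z <- blockZScore(nBlock = c(50L, 50L), nNoise = 100L, nSamples = 12L,
                   seed = 14)
  net <- runCoexpression(z, power = 6, min_module_size = 30)
  mods <- moduleLabels(net)
  truthA <- grep("^B1_", rownames(z), value = TRUE)
  truthB <- grep("^B2_", rownames(z), value = TRUE)
  found <- setdiff(unique(mods), "grey")
  jacA <- max(vapply(found, function(m)
    setJaccard(names(mods)[mods == m], truthA), 0))
  jacB <- max(vapply(found, function(m)
    setJaccard(names(mods)[mods == m], truthB), 0))
  expect_gte(jacA, 0.8)
  expect_gte(jacB, 0.8)
  ## one coherent block -> one module holding (nearly) all genes
  z1 <- blockZScore(nBlock = 60L, nNoise = 0L, nSamples = 12L,
                    noiseSD = 0.15, seed = 15)
  net1 <- runCoexpression(z1, power = 6)
  expect_identical(setdiff(unique(moduleLabels(net1)), "grey"), "turquoise")
  expect_gte(sum(moduleLabels(net1) == "turquoise"), 55L)
  ## min size above the gene count -> everything grey
  netG <- runCoexpression(z1, power = 6, min_module_size = 100L)
  expect_true(all(moduleLabels(netG) == "grey"))
  expect_identical(ncol(moduleEigengenes(netG)), 0L)
})

test_that("eigengenes are unit-norm, SVD-consistent and orientation-fixed", {
  set.seed(16)
  prof <- rnorm(7)
  z <- rbind(t(vapply(1:5, function(i) prof + rnorm(7, sd = 1e-6),
                      numeric(7))),
             matrix(rnorm(7 * 3), 3, 7))
  rownames(z) <- c(sprintf("m%d", 1:5), sprintf("x%d", 1:3))
  colnames(z) <- sprintf("s%d", 1:7)
  mods <- setNames(c(rep("blue", 5), rep("grey", 3)), rownames(z))
  eg <- computeEigengenes(zscoreGenes(z), mods)
  expect_equal(sqrt(sum(eg[, "blue"]^2)), 1, tolerance = 1e-9)
  expect_equal(abs(cor(eg[, "blue"], prof)), 1, tolerance = 1e-6)
  ## oriented with average expression
  expect_gt(cor(eg[, "blue"], colMeans(zscoreGenes(z)[1:5, ])), 0)
  ## flipping every module gene leaves the reported eigengene invariant
  z2 <- z; z2[1:5, ] <- -z2[1:5, ]
  eg2 <- computeEigengenes(zscoreGenes(z2), mods)
  expect_equal(abs(cor(eg2[, "blue"], eg[, "blue"])), 1, tolerance = 1e-6)
  ## tiny case against a direct SVD oracle
  z3 <- zscoreGenes(matrix(c(1, 2, 3, 2, 4, 6.1, 0.5, 1, 1.4), 3, 3,
                           byrow = TRUE,
                           dimnames = list(c("a", "b", "c"),
                                           c("s1", "s2", "s3"))))
  eg3 <- computeEigengenes(z3, setNames(rep("m", 3), rownames(z3)))
  sv <- svd(z3)$v[, 1]
  expect_equal(abs(sum(eg3[, 1] * sv)), 1, tolerance = 1e-9)
})

test_that("module-trait statistics use the Student-t transform and BH grid", {
  set.seed(17)
  eg <- matrix(rnorm(11 * 3), 11, 3,
               dimnames = list(sprintf("s%d", 1:11),
                               c("blue", "brown", "grey60")))
  traits <- data.frame(self = eg[, "blue"], noise = rnorm(11),
                       sex = rep(c("F", "M"), c(5, 6)),
                       site = rep(c("a", "b", "c"), c(4, 4, 3)))
  mt <- moduleTraitCor(eg, traits)
  expect_equal(mt$cor["blue", "self"], 1, tolerance = 1e-12)
  expect_lt(mt$p["blue", "self"], 1e-12)
  expect_true(all(mt$fdr >= mt$p))
  ## multi-level covariate one-hot binarized
  expect_true(all(c("site.a", "site.b", "site.c") %in% colnames(mt$cor)))
  ## frozen closed form: r = 0.81, n = 11 -> t = 4.144, p = 2.51e-3
  expect_equal(corPValue(0.81, 11), 0.002508, tolerance = 2e-3)
})

test_that("module-trait p-values are calibrated under a permuted trait", {
  set.seed(18)
  z <- blockZScore(nBlock = 40L, nNoise = 0L, nSamples = 12L, seed = 19)
  net <- runCoexpression(z, power = 6)
  eg <- moduleEigengenes(net)
  pv <- vapply(1:500, function(i)
    moduleTraitCor(eg, data.frame(t = rnorm(nrow(eg))))$p[1, 1],
    numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene statistics and hub selection follow their definitions", {
  z <- blockZScore(nBlock = c(40L, 35L), nNoise = 30L, nSamples = 12L,
                   seed = 20)
  net <- runCoexpression(z, power = 6)
  trait <- moduleEigengenes(net)[, 1]
  stats <- geneStatistics(z, net, trait)
  ## a gene's MM equals cor with its own eigengene; check the top module
  m1 <- colnames(moduleEigengenes(net))[1]
  gi <- stats$gene[stats$module == m1][1]
  expect_equal(stats$MM[stats$gene == gi],
               cor(z[gi, ], moduleEigengenes(net)[, m1]))
  ## kIM matches brute-force scaled intramodular sums on a small module
  adj <- networkAdjacency(net)
  gm <- stats$gene[stats$module == m1]
  sums <- vapply(gm, function(g) sum(adj[g, setdiff(gm, g)]), 0)
  expect_equal(stats$kIM[match(gm, stats$gene)], unname(sums / max(sums)),
               tolerance = 1e-12)
  ## hub selection is a strict conjunction
  hubs <- hubGenes(stats, module = m1, mm_min = 0.7, kim_min = 0.7,
                   adj_min = 0.3)
  expect_true(all(hubs %in% gm))
  sFail <- stats
  sFail$max_adj[sFail$gene == hubs[1]] <- 0.1
  expect_false(hubs[1] %in% hubGenes(sFail, module = m1))
  ## thresholds at zero return the whole module
  expect_setequal(hubGenes(stats, module = m1, mm_min = -1, kim_min = -1,
                           adj_min = -1), gm)
  ## singleton module gets kIM 0
  z2 <- z[1:41, ]
  mods2 <- setNames(c(rep("blue", 40), "red"), rownames(z2))
  netS <- methods::new("CoexprNetwork",
                       correlation = cor(t(z2)), beta = 6,
                       adjacency = adjacencySigned(cor(t(z2)), 6),
                       tom = matrix(0, 0, 0), dendrogram = NULL,
                       modules = mods2,
                       eigengenes = computeEigengenes(z2, mods2),
                       powerTable = data.frame())
  sS <- geneStatistics(z2, netS, trait)
  expect_equal(sS$kIM[sS$module == "red"], 0)
  ## MM vs GS coupling: within the trait-defining module they correlate
  inM <- stats$module == m1
  expect_gt(cor(stats$MM[inM], stats$GS[inM]), 0)
})

test_that("edge lists export adjacency above threshold", {
  z <- blockZScore(nBlock = 35L, nNoise = 10L, nSamples = 12L, seed = 21)
  net <- runCoexpression(z, power = 6)
  el <- edgeList(net, module = "turquoise", adj_min = 0.3)
  adj <- networkAdjacency(net)
  expect_true(all(el$adjacency > 0.3))
  expect_equal(nrow(el),
               sum(upper.tri(adj[moduleLabels(net) == "turquoise",
                                 moduleLabels(net) == "turquoise"]) &
                     adj[moduleLabels(net) == "turquoise",
                         moduleLabels(net) == "turquoise"] > 0.3))
})
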