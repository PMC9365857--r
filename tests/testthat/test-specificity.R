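test_that("hub-gene grouping cuts the root split and labels the low group", {
  ## 3 clearly depressed samples among 8
  z <- matrix(rnorm(10 * 8, sd = 0.1), 10, 8,
              dimnames = list(sprintf("h%02d", 1:10), sprintf("s%d", 1:8)))
  z[, 1:3] <- z[, 1:3] - 2
  z[, 4:8] <- z[, 4:8] + 1
  part <- groupSamplesByHubGenes(z, rownames(z))
  expect_identical(unname(part[1:3]), factor(rep("low", 3),
                                             levels = c("high", "low"))[1:3])
  expect_identical(sum(part == "low"), 3L)
  ## permuting gene rows does not change a distance-based partition
  part2 <- groupSamplesByHubGenes(z[sample(10), ], rownames(z))
  expect_identical(part, part2)
  expect_error(groupSamplesByHubGenes(matrix(1, 4, 5,
                                             dimnames = list(letters[1:4],
                                                             LETTERS[1:5])),
                                      letters[1:4]),
               "degenerate")
})

test_that("the empirical p-value uses the count/total convention", {
  expect_equal(empiricalPValue(550, 10000), 0.055)
  expect_equal(empiricalPValue(0, 100), 0)
  expect_error(empiricalPValue(5, 0))
})

test_that("grouping permutation null counts unordered bipartition matches", {
  set.seed(28)
  ## a covariate present in all genes: any 10-gene draw reproduces the split
  z <- matrix(rnorm(60 * 8, sd = 0.05), 60, 8,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:8)))
  z[, 1:4] <- z[, 1:4] + 3
  part <- groupSamplesByHubGenes(z, rownames(z)[1:10])
  sg <- groupingPermutationP(z, part, n_genes = 10, n_perm = 50, seed = 1)
  expect_s4_class(sg, "SampleGrouping")
  expect_gt(empiricalP(sg), 0.95)
  ## n_perm = 1 reproducing the split gives exactly 1
  sg1 <- groupingPermutationP(z, part, n_genes = 10, n_perm = 1, seed = 2)
  expect_equal(empiricalP(sg1), 1)
  ## label swap of the observed partition changes nothing
  sw <- factor(ifelse(part == "low", "high", "low"))
  names(sw) <- names(part)
  sg2 <- groupingPermutationP(z, sw, n_genes = 10, n_perm = 50, seed = 1)
  expect_identical(sg2@nMatches, sg@nMatches)
  expect_error(groupingPermutationP(z, part, n_genes = 100, n_perm = 5),
               "exceeds")
})

test_that("grouping matches are rare when no structure is planted", {
  set.seed(29)
  rates <- vapply(1:30, function(i) {
    z <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("s%d", 1:8)))
    part <- groupSamplesByHubGenes(z, rownames(z)[1:10])
    empiricalP(groupingPermutationP(z, part, n_genes = 10, n_perm = 60,
                                    seed = i))
  }, numeric(1))
  ## null cohorts should only occasionally reproduce an arbitrary split
  expect_lt(median(rates), 0.5)
  expect_gt(mean(rates), 0)     # but matches do occur at some base rate
})

test_that("auxiliary-module selection is a strict conjunction of thresholds", {
  stats <- data.frame(
    gene = c("t1", "t2", "t3", "x1"),
    module = c("black", "black", "black", "grey"),
    MM = c(0.9, 0.3, 0.8, 0.95),
    GS = c(0.8, 0.6, 0.4, 0.9),
    GS_p = c(0.001, 0.01, 0.2, 0.001),
    kIM = 1, max_adj = 1)
  targets <- c("t1", "t2", "t3")
  expect_identical(defineAuxiliaryModule(stats, targets), "t1")
  ## thresholds 0/1/0 admit every module target
  expect_setequal(defineAuxiliaryModule(stats, targets, gs_min = -1,
                                        gs_p_max = 1, mm_min = -1),
                  targets)
  ## GS 0.6 with MM 0.3 is excluded
  expect_false("t2" %in% defineAuxiliaryModule(stats, targets))
})

test_that("cor.kME preservation is exact for the reference and null elsewhere", {
  set.seed(30)
  f <- rnorm(9)
  ref <- t(vapply(1:12, function(i) f + rnorm(9, sd = 0.3), numeric(9)))
  rownames(ref) <- sprintf("a%02d", 1:12)
  colnames(ref) <- sprintf("s%d", 1:9)
  copy <- ref + matrix(rnorm(length(ref), sd = 1e-9), nrow(ref))
  pres <- preservationCorKME(list(ref = ref, copy = copy), "ref",
                             rownames(ref))
  expect_equal(pres$cor_kme[pres$cluster == "ref"], 1)
  expect_equal(pres$cor_kme[pres$cluster == "copy"], 1, tolerance = 1e-4)
  ## genes independently permuted across samples: cor_kme centred on zero
  rs <- vapply(1:30, function(i) {
    perm <- t(apply(ref, 1, sample))
    colnames(perm) <- colnames(ref)
    preservationCorKME(list(ref = ref, p = perm), "ref",
                       rownames(ref))$cor_kme[2]
  }, numeric(1))
  expect_gt(t.test(rs)$p.value, 0.01)
  ## clusters with < 2 usable auxiliary genes are excluded
  droppy <- ref; droppy[-1, ] <- 0
  pres2 <- preservationCorKME(list(ref = ref, d = droppy), "ref",
                              rownames(ref))
  expect_false("d" %in% pres2$cluster)
})

test_that("pairwise correlation panels mask non-significant entries", {
  set.seed(31)
  ## 3 samples: nearly everything masked
  tiny <- matrix(rnorm(5 * 3), 5, 3,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:3)))
  panel <- pairwiseCorrelationPanel(list(c0 = tiny), rownames(tiny))
  offd <- panel$panels$c0[upper.tri(panel$panels$c0)]
  expect_gt(mean(is.na(offd)), 0.5)
  ## an identical gene pair stays unmasked at cor 1
  dup <- rbind(g1 = rnorm(8), g2 = 0, g3 = rnorm(8))
  dup["g2", ] <- dup["g1", ]
  colnames(dup) <- sprintf("s%d", 1:8)
  p2 <- pairwiseCorrelationPanel(list(c1 = dup), rownames(dup))
  expect_equal(p2$panels$c1["g1", "g2"], 1, tolerance = 1e-12)
  ## a cluster with no significant pair is flagged
  set.seed(32)
  nul <- matrix(rnorm(3 * 4), 3, 4,
                dimnames = list(sprintf("g%d", 1:3), sprintf("s%d", 1:4)))
  p3 <- pairwiseCorrelationPanel(list(n = nul), rownames(nul))
  if (all(is.na(p3$panels$n[upper.tri(p3$panels$n)])))
    expect_identical(p3$no_signif, "n")
})

test_that("per-cluster variability localises exclusive expression", {
  set.seed(33)
  n <- 300
  cl <- rep(c("a", "b"), each = n / 2)
  sm <- rep(sprintf("s%d", 1:6), length.out = n)
  counts <- rbind(
    gOnlyB = c(rpois(n / 2, 0.01), rpois(n / 2, 6)),
    gFlat = rpois(n, 3),
    gFlat2 = rpois(n, 1))
  pcv <- perClusterVariability(counts, sm, cl)
  am <- pcv$argmax
  expect_identical(am$sc_raw_var[am$gene == "gOnlyB"], "b")
  expect_identical(am$pb_zscore_var[am$gene == "gOnlyB"], "b")
})

test_that("variance fold-change permutation test behaves at both extremes", {
  set.seed(34)
  universe <- sprintf("g%03d", 1:300)
  vB <- setNames(rexp(300) + 0.5, universe)
  targets <- sample(universe, 14)
  ## identical inputs: all fold changes 1, p not small
  same <- varianceFoldChangeTest(vB, vB, targets, n_perm = 2000,
                                 n_boot = 200, seed = 1)
  expect_true(all(same$fc == 1))
  expect_gt(same$p, 0.05)
  ## planted 3x inflation: p at the permutation floor
  vA <- vB
  vA[targets] <- vA[targets] * 3
  infl <- varianceFoldChangeTest(vA, vB, targets, n_perm = 2000,
                                 n_boot = 200, seed = 1)
  expect_equal(infl$p, 1 / 2001, tolerance = 1e-12)
  expect_equal(infl$median, 3, tolerance = 1e-9)
  expect_true(infl$ci95[1] <= infl$mean && infl$mean <= infl$ci95[2])
  ## single target: mean = median = its fold change
  one <- varianceFoldChangeTest(vA, vB, targets[1], n_perm = 100,
                                n_boot = 50, seed = 1)
  expect_equal(one$mean, one$median)
  expect_equal(unname(one$mean), unname(vA[targets[1]] / vB[targets[1]]))
  ## zero-variance denominators are dropped with a warning
  vB2 <- vB; vB2[targets[1]] <- 0
  expect_warning(varianceFoldChangeTest(vA, vB2, targets[1:3], n_perm = 100,
                                        n_boot = 50, seed = 1),
                 "zero denominator")
})
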