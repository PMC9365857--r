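#' Select the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power, the signed adjacency is formed, per-gene
#' connectivities \eqn{k_i = \sum_{j \ne i} a_{ij}} are binned into 10 bins,
#' and log10(frequency) is regressed on log10(mean connectivity); the signed
#' fit index is \eqn{-sign(slope) R^2}. The chosen power is the smallest one
#' whose signed fit reaches \code{rsq_cut}, falling back to the power with
#' the maximal signed fit when none does.
#'
#' @param zscore genes-by-samples standardised expression.
#' @param powers candidate powers.
#' @param rsq_cut signed scale-free fit threshold.
#' @return list with \code{beta}, \code{fit_table} (power, signed R-squared,
#'   slope, mean connectivity) and \code{reached} (logical).
#' @export
pickSoftThreshold <- function(zscore, powers = 1:20, rsq_cut = 0.85) {
  cc <- cor(t(as.matrix(zscore)))
  base <- (1 + cc) / 2
  diag(base) <- 1
  rows <- lapply(powers, function(b) {
    a <- base^b
    k <- rowSums(a) - 1
    fit <- .scaleFreeFit(k)
    data.frame(power = b, signed_rsq = fit$rsq, slope = fit$slope,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$signed_rsq >= rsq_cut)
  reached <- length(hit) > 0
  beta <- if (reached) tab$power[hit[1]] else tab$power[which.max(tab$signed_rsq)]
  list(beta = beta, fit_table = tab, reached = reached)
}

.scaleFreeFit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins || diff(range(k)) == 0)
    return(list(rsq = NA_real_, slope = NA_real_))
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  km <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(km)
  if (sum(ok) < 3) return(list(rsq = NA_real_, slope = NA_real_))
  fit <- lm(log10(freq[ok]) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  sl <- coef(fit)[2]
  list(rsq = -sign(sl) * r2, slope = unname(sl))
}

#' Signed adjacency from a correlation matrix
#'
#' \eqn{a_{ij} = ((1 + cor_{ij})/2)^\beta}: perfectly correlated genes get
#' adjacency 1, perfectly anti-correlated genes 0, and uncorrelated genes
#' \eqn{0.5^\beta}.
#'
#' @param cc gene-gene Pearson correlation matrix.
#' @param beta soft-threshold power.
#' @return adjacency matrix with unit diagonal.
#' @export
adjacencySigned <- function(cc, beta) {
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_{u \ne i} a_{iu}} and unit diagonal. Computed with a
#' single matrix product; equals the brute-force triple loop to numerical
#' precision.
#'
#' @param adjacency symmetric adjacency matrix with unit diagonal.
#' @return the TOM, entries in [0,1], diagonal 1.
#' @export
tomMatrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric")
  k <- rowSums(a) - diag(a)
  numer <- a %*% a - 2 * a * rep(diag(a), each = nrow(a))  # remove u=i, u=j
  numer <- numer + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- numer / denom
  diag(tom) <- 1
  tom
}

# recursive dendrogram-only dynamic branch cut; returns integer labels
# (0 = unassigned). Branch splitting re-clusters the branch's cophenetic
# distances and cuts at cutFrac x the local top merge height.
.dynamicTreeCut <- function(hc, minSize, cutFrac = 0.99) {
  n <- length(hc$order)
  labels <- integer(n)
  if (n < minSize) return(labels)
  cop <- as.matrix(stats::cophenetic(hc))
  nextId <- 0L
  cutRecurse <- function(leafIdx) {
    if (length(leafIdx) < minSize) return(invisible(NULL))
    if (length(leafIdx) < 3L) {
      nextId <<- nextId + 1L
      labels[leafIdx] <<- nextId
      return(invisible(NULL))
    }
    sub <- hclust(as.dist(cop[leafIdx, leafIdx]), method = "average")
    if (max(sub$height) <= 0) {
      nextId <<- nextId + 1L
      labels[leafIdx] <<- nextId
      return(invisible(NULL))
    }
    memb <- cutree(sub, h = cutFrac * max(sub$height))
    parts <- lapply(split(seq_along(leafIdx), memb), function(i) leafIdx[i])
    big <- parts[vapply(parts, length, 1L) >= minSize]
    if (length(big) <= 1L) {
      nextId <<- nextId + 1L
      labels[leafIdx] <<- nextId
    } else {
      for (p in big) cutRecurse(p)
    }
    invisible(NULL)
  }
  memb <- cutree(hc, h = cutFrac * max(hc$height))
  parts <- lapply(split(seq_len(n), memb), identity)
  for (p in parts) if (length(p) >= minSize) cutRecurse(p)
  labels
}

#' Detect co-expression modules by dynamic tree cut
#'
#' Average-linkage clustering on 1-TOM, a recursive dendrogram branch cut
#' (branches of at least \code{min_module_size} leaves, adaptive cut at
#' \code{0.99 x} the local merge height), colour-coded labels ordered by
#' decreasing module size, and a final merge of modules whose eigengene
#' dissimilarity (1 - correlation) is below \code{merge_height}. Unassigned
#' genes are labelled \code{"grey"}.
#'
#' Assigned genes are then refined by module-membership significance: the
#' eigengene of each module is re-anchored on the module's core (its
#' \code{min_module_size} most intramodularly connected genes), and a gene
#' stays in the module only if its kME against that core eigengene is
#' significantly positive at one-sided p < \code{kme_refine_p} (Student t,
#' n-2 df). With few samples chance correlations are large and dendrogram
#' branches accrete unrelated genes; the core anchoring makes the stage
#' robust even when a branch is dominated by such chaining. The default
#' level 0.005 keeps the expected number of chance survivors (p x n_genes,
#' about 7 of 1,500) well below the minimum module size. Refinement is
#' skipped for fewer than 6 samples or when \code{kme_refine_p = NULL}.
#'
#' @param tom topological overlap matrix.
#' @param zscore genes-by-samples standardised expression (for eigengenes).
#' @param min_module_size smallest branch that can become a module.
#' @param merge_height eigengene dissimilarity below which modules merge.
#' @param kme_refine_p one-sided significance level of the kME refinement.
#' @param adjacency optional signed adjacency used to rank intramodular
#'   connectivity for the refinement core; the TOM is used when absent.
#' @return list with \code{modules} (named character vector),
#'   \code{eigengenes} (samples x modules), and \code{dendrogram}.
#' @export
detectModules <- function(tom, zscore, min_module_size = 30L,
                          merge_height = 0.25, kme_refine_p = 0.005,
                          adjacency = NULL) {
  genes <- rownames(tom)
  hc <- hclust(as.dist(1 - tom), method = "average")
  lab <- .dynamicTreeCut(hc, min_module_size)
  if (all(lab == 0L)) {
    mods <- setNames(rep("grey", length(lab)), genes)
    return(list(modules = mods,
                eigengenes = matrix(0, ncol(zscore), 0,
                                    dimnames = list(colnames(zscore), NULL)),
                dendrogram = hc))
  }
  repeat {
    eg <- .eigengeneMatrix(zscore, lab)
    if (ncol(eg) < 2L) break
    dis <- 1 - cor(eg)
    diag(dis) <- Inf
    mn <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    if (dis[mn[1], mn[2]] >= merge_height) break
    a <- as.integer(colnames(eg)[mn[1]]); b <- as.integer(colnames(eg)[mn[2]])
    lab[lab == max(a, b)] <- min(a, b)
  }
  ## kME-significance refinement of branch assignments, anchored on each
  ## module's most connected core
  n <- ncol(zscore)
  if (!is.null(kme_refine_p) && n >= 6L) {
    W <- if (is.null(adjacency)) tom else adjacency
    tcrit <- stats::qt(1 - kme_refine_p, df = n - 2)
    rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
    for (iter in 1:4) {
      ids <- unique(lab[lab > 0])
      if (length(ids) == 0L) break
      changed <- FALSE
      for (id in ids) {
        gi <- which(lab == id)
        if (length(gi) < 2L) { lab[gi] <- 0L; changed <- TRUE; next }
        conn <- rowSums(W[gi, gi, drop = FALSE])
        core <- gi[order(-conn)][seq_len(min(min_module_size, length(gi)))]
        eg <- .firstEigengene(as.matrix(zscore)[core, , drop = FALSE])
        kme <- as.vector(cor(t(as.matrix(zscore)[gi, , drop = FALSE]), eg))
        bad <- gi[is.na(kme) | kme < rcrit]
        if (length(bad)) { lab[bad] <- 0L; changed <- TRUE }
      }
      if (!changed) break
    }
    if (all(lab == 0L)) {
      mods <- setNames(rep("grey", length(lab)), genes)
      return(list(modules = mods,
                  eigengenes = matrix(0, n, 0,
                                      dimnames = list(colnames(zscore), NULL)),
                  dendrogram = hc))
    }
  }
  ## order by size and colour-code
  ids <- names(sort(table(lab[lab > 0]), decreasing = TRUE))
  cols <- moduleColours(length(ids))
  mods <- rep("grey", length(lab))
  for (i in seq_along(ids)) mods[lab == as.integer(ids[i])] <- cols[i]
  names(mods) <- genes
  eg <- computeEigengenes(zscore, setNames(mods, genes))
  list(modules = mods, eigengenes = eg, dendrogram = hc)
}

# internal eigengenes keyed by integer label
.eigengeneMatrix <- function(zscore, lab) {
  ids <- sort(unique(lab[lab > 0]))
  eg <- vapply(ids, function(id)
    .firstEigengene(zscore[lab == id, , drop = FALSE]),
    numeric(ncol(zscore)))
  colnames(eg) <- as.character(ids)
  eg
}

# first right-singular vector of the row-standardised submatrix, oriented to
# correlate positively with the average module expression; unit norm
.firstEigengene <- function(sub) {
  zs <- zscoreRows(as.matrix(sub))
  sv <- svd(zs, nu = 0, nv = 1)
  v <- sv$v[, 1]
  avg <- colMeans(zs)
  if (sum(v * avg) < 0) v <- -v
  v
}

#' Standard module colour sequence
#'
#' Colour labels assigned to modules by decreasing size; \code{"grey"} is
#' reserved for unassigned genes.
#'
#' @param n number of colours needed.
#' @return character vector of length \code{n}.
#' @export
moduleColours <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue",
            "saddlebrown", "steelblue", "paleturquoise", "violet",
            "darkolivegreen", "darkmagenta")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

#' Module eigengenes from expression and labels
#'
#' The eigengene of a module is the first right-singular direction of its
#' row-standardised gene submatrix (unit norm over samples), sign-oriented
#' to correlate positively with the module's average standardised
#' expression.
#'
#' @param zscore genes-by-samples standardised expression.
#' @param modules named per-gene module labels; \code{"grey"} is skipped.
#' @return samples-by-modules eigengene matrix.
#' @export
computeEigengenes <- function(zscore, modules) {
  zscore <- as.matrix(zscore)
  ids <- setdiff(unique(modules), "grey")
  ids <- names(sort(table(modules[modules %in% ids]), decreasing = TRUE))
  eg <- vapply(ids, function(id)
    .firstEigengene(zscore[names(modules)[modules == id], , drop = FALSE]),
    numeric(ncol(zscore)))
  if (length(ids) == 0L)
    eg <- matrix(0, ncol(zscore), 0)
  else colnames(eg) <- ids
  rownames(eg) <- colnames(zscore)
  eg
}

#' Build a signed weighted co-expression network
#'
#' Full pipeline: Pearson correlation over samples, soft-threshold selection
#' (unless \code{power} is given), signed adjacency, TOM, average-linkage
#' dendrogram on 1-TOM, dynamic tree cut with eigengene merging, and module
#' eigengenes.
#'
#' @param zscore genes-by-samples standardised pseudo-bulk expression.
#' @param power \code{"auto"} or an integer soft power.
#' @param powers candidate powers for the automatic search.
#' @param min_module_size,merge_height,kme_refine_p see
#'   \code{\link{detectModules}}.
#' @return a \linkS4class{CoexprNetwork}.
#' @export
runCoexpression <- function(zscore, power = "auto", powers = 1:20,
                            min_module_size = 30L, merge_height = 0.25,
                            kme_refine_p = 0.005) {
  zscore <- as.matrix(zscore)
  keep <- matrixStats::rowSds(zscore) > .Machine$double.eps
  zs <- zscore[keep, , drop = FALSE]
  cc <- cor(t(zs))
  pt <- data.frame()
  if (identical(power, "auto")) {
    ps <- pickSoftThreshold(zs, powers = powers)
    beta <- ps$beta
    pt <- ps$fit_table
  } else beta <- as.numeric(power)
  adj <- adjacencySigned(cc, beta)
  tom <- tomMatrix(adj)
  det <- detectModules(tom, zs, min_module_size, merge_height, kme_refine_p,
                       adjacency = adj)
  mods <- setNames(rep("grey", nrow(zscore)), rownames(zscore))
  mods[names(det$modules)] <- det$modules
  methods::new("CoexprNetwork", correlation = cc, beta = beta,
               adjacency = adj, tom = tom, dendrogram = det$dendrogram,
               modules = mods, eigengenes = det$eigengenes, powerTable = pt)
}

#' Module-trait correlation matrix
#'
#' Pearson correlation of every module eigengene with every trait, two-sided
#' Student-t p-values with n-2 degrees of freedom, and Benjamini-Hochberg
#' adjustment across the whole module-by-trait grid. Character/factor traits
#' are binarized (two levels -> 0/1; more levels -> one-hot columns).
#'
#' @param eigengenes samples-by-modules matrix.
#' @param traits data.frame of sample traits (numeric, factor or character).
#' @return list of module-by-trait matrices \code{cor}, \code{p}, \code{fdr}.
#' @export
moduleTraitCor <- function(eigengenes, traits) {
  tm <- .binarizeTraits(traits)
  cc <- cor(eigengenes, tm)
  p <- corPValue(cc, nrow(eigengenes))
  fdr <- matrix(p.adjust(p, "BH"), nrow(p), ncol(p), dimnames = dimnames(p))
  list(cor = cc, p = p, fdr = fdr)
}

.binarizeTraits <- function(traits) {
  traits <- as.data.frame(traits)
  cols <- list()
  for (nm in colnames(traits)) {
    v <- traits[[nm]]
    if (is.numeric(v)) { cols[[nm]] <- v; next }
    v <- factor(v)
    if (nlevels(v) <= 2L) cols[[nm]] <- as.numeric(v) - 1
    else for (lv in levels(v)) cols[[paste0(nm, ".", lv)]] <-
        as.numeric(v == lv)
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(traits)
  out
}

#' Per-gene module statistics: MM, GS, kIM
#'
#' Module membership (kME) is the correlation of a gene with its own
#' module's eigengene; gene significance is the correlation with an external
#' trait (with a Student-t p-value); intramodular connectivity is the sum of
#' a gene's adjacencies to the other genes of its module, scaled by the
#' module maximum; the gene's maximal intramodular adjacency is recorded for
#' the hub-edge criterion.
#'
#' @param zscore genes-by-samples standardised expression.
#' @param network a \linkS4class{CoexprNetwork}.
#' @param trait numeric per-sample trait (e.g. driver pseudo-bulk
#'   expression).
#' @return data.frame with columns \code{gene}, \code{module}, \code{MM},
#'   \code{GS}, \code{GS_p}, \code{kIM}, \code{max_adj}.
#' @export
geneStatistics <- function(zscore, network, trait) {
  zscore <- as.matrix(zscore)
  mods <- moduleLabels(network)
  eg <- moduleEigengenes(network)
  adj <- networkAdjacency(network)
  genes <- names(mods)
  n <- ncol(zscore)
  mm <- rep(NA_real_, length(genes))
  kim <- numeric(length(genes))
  mx <- numeric(length(genes))
  for (id in setdiff(unique(mods), "grey")) {
    gi <- which(mods == id)
    if (id %in% colnames(eg))
      mm[gi] <- as.vector(cor(t(zscore[genes[gi], , drop = FALSE]), eg[, id]))
    sub <- adj[genes[gi], genes[gi], drop = FALSE]
    if (length(gi) > 1L) {
      k <- rowSums(sub) - diag(sub)
      kim[gi] <- if (max(k) > 0) k / max(k) else 0
      diag(sub) <- 0
      mx[gi] <- matrixStats::rowMaxs(sub)
    }
  }
  gs <- as.vector(cor(t(zscore[genes, , drop = FALSE]), trait))
  data.frame(gene = genes, module = unname(mods), MM = mm, GS = gs,
             GS_p = corPValue(gs, n), kIM = kim, max_adj = mx,
             row.names = NULL)
}

#' Hub genes of a module
#'
#' Genes with module membership, scaled intramodular connectivity and
#' maximal intramodular adjacency all strictly above their thresholds.
#'
#' @param stats output of \code{\link{geneStatistics}}.
#' @param module module label to extract hubs from (default: all modules).
#' @param mm_min,kim_min,adj_min thresholds.
#' @return character vector of hub gene ids.
#' @export
hubGenes <- function(stats, module = NULL, mm_min = 0.7, kim_min = 0.7,
                     adj_min = 0.3) {
  s <- stats
  if (!is.null(module)) s <- s[s$module %in% module, , drop = FALSE]
  else s <- s[s$module != "grey", , drop = FALSE]
  ok <- !is.na(s$MM) & s$MM > mm_min & s$kIM > kim_min & s$max_adj > adj_min
  s$gene[ok]
}

#' Export the hub-edge list of a network
#'
#' Edges (gene pairs) with adjacency above a threshold, for network plots.
#'
#' @param network a \linkS4class{CoexprNetwork}.
#' @param module restrict to genes of this module (optional).
#' @param adj_min adjacency threshold.
#' @return data.frame with columns \code{gene1}, \code{gene2},
#'   \code{adjacency}.
#' @export
edgeList <- function(network, module = NULL, adj_min = 0.3) {
  adj <- networkAdjacency(network)
  if (!is.null(module)) {
    g <- names(moduleLabels(network))[moduleLabels(network) %in% module]
    adj <- adj[g, g, drop = FALSE]
  }
  idx <- which(upper.tri(adj) & adj > adj_min, arr.ind = TRUE)
  data.frame(gene1 = rownames(adj)[idx[, 1]], gene2 = colnames(adj)[idx[, 2]],
             adjacency = adj[idx], row.names = NULL)
}
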