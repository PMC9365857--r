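#' @import methods
#' @importFrom stats cor dist hclust as.dist cutree sd var quantile median mad
#'   rnbinom rnorm rlnorm plogis qlogis pchisq pt pnorm p.adjust prcomp lm
#'   coef glm anova loess predict setNames rbinom runif aggregate
#' @importFrom utils head write.table read.table
NULL

#' Deterministic per-stage seed fan-out
#'
#' Derives an independent (deterministic) seed for a named pipeline stage
#' from one user seed, so toggling one stage does not shift another's
#' randomness. The result always fits a 32-bit integer.
#'
#' @param seed user-level integer seed.
#' @param stage stage name.
#' @return an integer seed.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 2654L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.geomMean <- function(x) exp(mean(log(x)))

.asCountMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, "counts")
  if (is(x, "sparseMatrix")) return(x)
  if (is.matrix(x)) return(x)
  stop("expected a matrix, sparse Matrix or SummarizedExperiment")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} with n-2 degrees
#' of freedom.
#'
#' @param r correlation value(s).
#' @param n number of paired observations.
#' @return two-sided p-value(s).
#' @export
corPValue <- function(r, n) {
  df <- n - 2
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(t), df = df, lower.tail = FALSE)
}

# Row-wise z-score with sample (n-1) sd; zero-variance rows become all-zero
# and are reported via the "flagged" attribute.
zscoreRows <- function(x) {
  m <- rowMeans(x)
  s <- matrixStats::rowSds(as.matrix(x))
  flagged <- s <= .Machine$double.eps
  s[flagged] <- 1
  z <- (x - m) / s
  z[flagged, ] <- 0
  attr(z, "zero_variance") <- rownames(x)[flagged]
  z
}

# Jaccard index of two gene sets
.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
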