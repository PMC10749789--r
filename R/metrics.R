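#' Pearson correlation coefficient
#'
#' Covariance of the two vectors divided by the product of their standard
#' deviations. Zero variance on either side makes the coefficient undefined;
#' a flagged \code{NaN} is returned and such genes are excluded from means
#' downstream.
#'
#' @param xTrue,xPred numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or \code{NaN} when undefined.
#' @export
pcc <- function(xTrue, xPred) {
  stopifnot(length(xTrue) == length(xPred), length(xTrue) >= 2L)
  mx <- mean(xTrue); my <- mean(xPred)
  cv <- mean((xTrue - mx) * (xPred - my))
  sx <- sqrt(mean((xTrue - mx)^2)); sy <- sqrt(mean((xPred - my)^2))
  if (sx == 0 || sy == 0) return(NaN)
  max(-1, min(1, cv / (sx * sy)))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2
#' degrees of freedom; |r| = 1 returns 0 by convention.
#'
#' @param r correlation coefficient.
#' @param n sample size (>= 3).
#' @return two-sided p-value.
#' @export
pccPvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  stopifnot(n >= 3L)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Rank genes by evidence of predictive correlation
#'
#' Genes are ordered by the mean over sections of \eqn{-\log_{10} p} of the
#' per-gene correlation between predicted and observed expression,
#' descending; ties break by gene name.
#'
#' @param report an \linkS4class{EvalReport}.
#' @return data.frame with columns \code{gene}, \code{meanNegLog10P},
#'   \code{meanPcc}, sorted.
#' @export
rankGenes <- function(report) {
  pv <- report@pvalues
  nl <- -log10(pmax(pv, 1e-300))
  m <- rowMeans(nl, na.rm = TRUE)
  mp <- rowMeans(report@pcc, na.rm = TRUE)
  ord <- order(-m, rownames(pv))
  data.frame(gene = rownames(pv)[ord], meanNegLog10P = m[ord],
             meanPcc = mp[ord], row.names = NULL)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' pair-counting contingency table. Invariant to label permutations; 1 for
#' identical partitions (including the degenerate single-cluster vs
#' single-cluster case, by convention).
#'
#' @param labelsA,labelsB partitions of the same n >= 2 items.
#' @return ARI in [-1, 1].
#' @export
ari <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB), length(labelsA) >= 2L)
  tab <- table(labelsA, labelsB)
  n <- length(labelsA)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)    # both partitions trivial
  (sij - expected) / (maxidx - expected)
}

#' Clustering evaluation against an annotation
#'
#' K-means on the predicted expression matrix (fixed seed), compared to the
#' reference spatial-domain partition with the adjusted Rand index.
#'
#' @param predExpr spots x genes predicted expression.
#' @param annotations reference partition, one label per spot.
#' @param k number of clusters (= number of annotated regions).
#' @param seed RNG seed for the K-means initialisation.
#' @param nstart K-means restarts.
#' @return ARI between the K-means clustering and the annotation.
#' @export
clusterEval <- function(predExpr, annotations, k, seed = 1L, nstart = 10L) {
  stopifnot(nrow(predExpr) == length(annotations))
  if (k > nrow(predExpr)) stop("k exceeds the number of spots")
  set.seed(seed)
  km <- stats::kmeans(predExpr, centers = k, nstart = nstart)
  ari(km$cluster, annotations)
}
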