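# Spot neighbourhood graph and graph attention. Each spot is connected to its
# four nearest neighbours by Euclidean distance on pixel coordinates; edge
# attention is a learned linear score of the transformed endpoint features,
# LeakyReLU'd and softmax-normalised over each spot's neighbourhood.

#' Build the k-nearest-neighbour spot graph
#'
#' Directed: an edge i -> j means j is among the k spots closest to i (self
#' excluded). Ties are broken by (distance, spot index) lexicographic order.
#' Duplicate coordinates are allowed; zero-length edges are flagged with a
#' warning.
#'
#' @param spots a \linkS4class{SpotTable} or data.frame with pixel (or array)
#'   coordinates.
#' @param k neighbours per spot (default 4); capped at N - 1.
#' @param coords \code{"pixel"} (default) or \code{"array"} coordinates.
#' @return A \linkS4class{SpotGraph}.
#' @export
buildKnnGraph <- function(spots, k = 4L, coords = c("pixel", "array")) {
  coords <- match.arg(coords)
  df <- if (is(spots, "SpotTable")) spotTable(spots) else spots
  xy <- if (coords == "pixel") cbind(df$pixel_x, df$pixel_y)
        else cbind(df$array_x, df$array_y)
  N <- nrow(xy)
  if (N < 2L) stop("need at least two spots")
  if (any(!is.finite(xy))) stop("coordinates must be finite")
  kk <- min(as.integer(k), N - 1L)
  D <- as.matrix(stats::dist(xy))
  from <- integer(N * kk); to <- integer(N * kk); dd <- numeric(N * kk)
  for (i in seq_len(N)) {
    cand <- setdiff(seq_len(N), i)
    ord <- cand[order(D[i, cand], cand)][seq_len(kk)]
    at <- (i - 1L) * kk + seq_len(kk)
    from[at] <- i; to[at] <- ord; dd[at] <- D[i, ord]
  }
  if (any(dd == 0))
    warning("zero-length edge(s): duplicate spot coordinates present")
  new("SpotGraph", nNodes = N, edges = cbind(from = from, to = to),
      distances = dd, k = kk)
}

#' Initialise graph-attention parameters
#'
#' @param M input feature length (the flattened per-spot encoder output).
#' @param mOut output feature length of the updated embedding.
#' @param nGenes size of the gene panel for the expression head.
#' @param seed optional RNG seed.
#' @return list with the shared transform \code{Wh} (M x M), scorer halves
#'   \code{a1}, \code{a2} (M x 1 each), combine weights \code{omega}
#'   (2M x mOut) and bias \code{beta} (1 x mOut), and the expression head
#'   \code{Wout} (mOut x nGenes), \code{bout}.
#' @export
gatParams <- function(M, mOut = M, nGenes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list(Wh = matrix(stats::rnorm(M * M, sd = sqrt(1 / M)), M, M),
            a1 = matrix(stats::rnorm(M, sd = sqrt(1 / M)), M, 1),
            a2 = matrix(stats::rnorm(M, sd = sqrt(1 / M)), M, 1),
            omega = matrix(stats::rnorm(2 * M * mOut, sd = sqrt(1 / (2 * M))),
                           2 * M, mOut),
            beta = matrix(0, 1, mOut))
  if (!is.null(nGenes)) {
    p$Wout <- matrix(stats::rnorm(mOut * nGenes, sd = sqrt(1 / mOut)),
                     mOut, nGenes)
    p$bout <- matrix(0, 1, nGenes)
  }
  p
}

#' Raw edge attention scores
#'
#' \eqn{e_{ij} = a_1^T W_h h_i + a_2^T W_h h_j}: a single-layer linear scorer
#' on the concatenated transformed endpoint features (the LeakyReLU belongs
#' to the normalisation step, see \code{\link{normalizeAttention}}).
#'
#' @param h N x M node feature matrix.
#' @param graph a \linkS4class{SpotGraph}.
#' @param params from \code{\link{gatParams}}.
#' @return numeric vector of scores, one per directed edge (edge order of the
#'   graph).
#' @export
edgeScores <- function(h, graph, params) {
  if (ncol(h) != nrow(params$Wh)) stop("feature length does not match params")
  Hw <- h %*% params$Wh
  e <- graph@edges
  as.vector(Hw[e[, 1], , drop = FALSE] %*% params$a1 +
            Hw[e[, 2], , drop = FALSE] %*% params$a2)
}

#' Normalise edge scores into attention coefficients
#'
#' \eqn{\alpha_{ij} = \mathrm{softmax}_{j \in \Omega(v_i)}
#' (\mathrm{LeakyReLU}(e_{ij}))}; coefficients sum to 1 over each spot's
#' neighbourhood.
#'
#' @param e edge scores from \code{\link{edgeScores}}.
#' @param graph the \linkS4class{SpotGraph} the scores were computed on.
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return numeric vector of attention coefficients, parallel to the edges.
#' @export
normalizeAttention <- function(e, graph, slope = 0.2) {
  z <- ifelse(e > 0, e, slope * e)
  src <- graph@edges[, 1]
  mx <- tapply(z, src, max)[as.character(src)]
  ez <- exp(z - mx)
  tot <- tapply(ez, src, sum)[as.character(src)]
  as.vector(ez / tot)
}

#' Aggregate neighbour features
#'
#' \eqn{h_{\Omega(v_i)} = \sum_{t \in \Omega(v_i)} \alpha_{it} h_t}; the
#' result lies in the convex hull of the neighbour features.
#'
#' @param h N x M node features.
#' @param alpha normalised attention coefficients (per edge).
#' @param graph the \linkS4class{SpotGraph}.
#' @return N x M aggregated neighbourhood features.
#' @export
aggregateNeighbors <- function(h, alpha, graph) {
  e <- graph@edges
  out <- rowsum((h[e[, 2], , drop = FALSE]) * alpha, e[, 1])
  res <- matrix(0, graph@nNodes, ncol(h))
  res[as.integer(rownames(out)), ] <- out
  res
}

#' Update node embeddings
#'
#' \eqn{\mathrm{ELU}(\mathrm{concat}(h_i, h_{\Omega(v_i)})\,\omega + \beta)}.
#'
#' @param h N x M node features.
#' @param hOmega N x M aggregated neighbourhood features.
#' @param params from \code{\link{gatParams}} (\code{omega}, \code{beta}).
#' @return N x mOut updated embeddings.
#' @export
updateEmbedding <- function(h, hOmega, params) {
  z <- sweep(cbind(h, hOmega) %*% params$omega, 2, as.vector(params$beta), "+")
  ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
}

#' Linear expression head
#'
#' Projects per-spot embeddings to the gene panel.
#'
#' @param h N x mOut embeddings.
#' @param params list with \code{Wout} (mOut x nGenes) and \code{bout}.
#' @return N x nGenes predicted expression.
#' @export
expressionHead <- function(h, params) {
  sweep(h %*% params$Wout, 2, as.vector(params$bout), "+")
}

# ---- tape version -----------------------------------------------------------
# h: (N x M) node; graph edges assumed ordered by source with constant
# out-degree kk. Returns the updated (N x mOut) embedding node.
.gat_fwd <- function(tape, h, pget, prefix, graph, slope = 0.2) {
  e <- graph@edges
  N <- graph@nNodes
  kk <- graph@k
  Hw <- ag_matmul(h, pget(paste0(prefix, ".Wh")))
  si <- ag_matmul(ag_rows(Hw, e[, 1]), pget(paste0(prefix, ".a1")))
  sj <- ag_matmul(ag_rows(Hw, e[, 2]), pget(paste0(prefix, ".a2")))
  s <- ag_leakyrelu(ag_add(si, sj), slope)
  # per-source softmax: edges are grouped by source, kk each -> reshape
  smat <- ag_t(ag_reshape(s, kk, N))            # N x kk (row i = edges of i)
  alpha <- ag_softmax_rows(smat)
  aflat <- ag_reshape(ag_t(alpha), N * kk, 1L)  # back to edge order
  hn <- ag_rowmul(ag_rows(h, e[, 2]), aflat)
  hom <- ag_rowsum_groups(hn, e[, 1], N)
  z <- ag_addbias(ag_matmul(ag_cbind(h, hom), pget(paste0(prefix, ".omega"))),
                  pget(paste0(prefix, ".beta")))
  ag_elu(z)
}
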