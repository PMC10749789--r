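# Capsule stage: primary capsules from the convolutional feature map, the
# squash activation, and one round of self-attention routing. Capsules are
# vector units whose norm (bounded in [0, 1) by squash) encodes presence and
# whose direction encodes pose; routing weights predictions by their mutual
# agreement rather than by iterative dynamic routing.

#' Squash activation
#'
#' \eqn{u = (1 - e^{-\|s\|}) \, s / \|s\|}; the zero vector maps to zero (the
#' continuous limit). Norms of the output always lie in [0, 1).
#'
#' @param s a capsule vector, or a matrix with one capsule per row.
#' @return same shape as \code{s}.
#' @export
squash <- function(s) {
  vec <- is.null(dim(s))
  m <- if (vec) matrix(s, 1) else s
  tp <- ag_tape()
  out <- ag_val(ag_squash_rows(ag_const(tp, m)))
  if (vec) as.vector(out) else out
}

#' Primary capsule layer
#'
#' ReLU k x k convolution to C channels followed by a depthwise (per-channel)
#' k x k convolution, both stride 1 with zero padding; the resulting
#' \code{h x w x C} map is regrouped into \code{h*w*(C/capsDim)} primary
#' capsules of dimension \code{capsDim} (channels within a spatial cell are
#' split into groups of \code{capsDim}).
#'
#' @param featureMap \code{h x w x C} array (channels last).
#' @param params list with \code{Wconv} (\code{(k^2 C) x C}), \code{bconv}
#'   (\code{1 x C}) and \code{Wdw} (\code{k^2 x C}); see
#'   \code{\link{capsuleConvParams}}.
#' @param capsDim capsule dimensionality d; must divide C.
#' @return \code{n x d} matrix of primary capsules (pre-squash).
#' @export
primaryCapsules <- function(featureMap, params, capsDim) {
  d <- dim(featureMap)
  h <- d[1]; w <- d[2]; C <- d[3]
  if (C %% capsDim != 0) stop("capsDim must divide the channel count")
  tp <- ag_tape()
  x <- ag_const(tp, matrix(featureMap, h * w, C))
  pget <- .const_pget(tp, params, "caps")
  out <- .caps_primary(tp, x, pget, "caps", h, w, 1L, C, capsDim,
                       k = as.integer(sqrt(nrow(params$Wdw))))
  ag_val(out)
}

#' Initialise the primary-capsule convolution parameters
#'
#' @param C channel count of the incoming feature map (kept by both convs).
#' @param kernelSize spatial kernel size.
#' @param seed optional RNG seed.
#' @return list with \code{Wconv}, \code{bconv}, \code{Wdw}.
#' @export
capsuleConvParams <- function(C, kernelSize = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k2 <- kernelSize^2
  list(Wconv = matrix(stats::rnorm(k2 * C * C, sd = sqrt(2 / (k2 * C))), k2 * C, C),
       bconv = matrix(0, 1, C),
       Wdw = matrix(stats::rnorm(k2 * C, sd = sqrt(2 / k2)), k2, C))
}

# tape version: x ((P*h*w) x C) -> capsules ((P*ncaps) x d), patch-major with
# capsule index fast. Capsule c within a patch = (pix - 1) * (C/d) + group.
.caps_primary <- function(tape, x, pget, prefix, h, w, P, C, capsDim, k = 3L,
                          pool = 1L, cache = NULL) {
  k2 <- k * k
  key <- sprintf("idx.%d.%d.%d.%d", h, w, k, P)
  idx <- if (!is.null(cache)) {
    if (is.null(cache[[key]])) cache[[key]] <- im2col_index(h, w, k, P)
    cache[[key]]
  } else im2col_index(h, w, k, P)
  f <- ag_relu(ag_addbias(ag_matmul(ag_im2col(x, idx),
                                    pget(paste0(prefix, ".Wconv"))),
                          pget(paste0(prefix, ".bconv"))))
  # depthwise conv: scale im2col columns by vec(Wdw) then sum offsets per channel
  fc <- ag_im2col(f, idx)
  Wdw <- pget(paste0(prefix, ".Wdw"))
  G2 <- matrix(0, k2 * C, C)
  for (ch in seq_len(C)) G2[(ch - 1L) * k2 + seq_len(k2), ch] <- 1
  dw <- ag_matmul(ag_colmul(fc, ag_reshape(Wdw, 1L, k2 * C)),
                  ag_const(tape, G2))
  hh <- h; ww <- w
  if (pool > 1L) {
    grp <- .pool_groups(h, w, pool, P)
    dw <- ag_rowsum_groups(dw, grp, P * (h %/% pool) * (w %/% pool), average = TRUE)
    hh <- h %/% pool; ww <- w %/% pool
  }
  # regroup (pixels x channels) into capsule rows
  .caps_regroup(dw, hh * ww, P, C, capsDim)
}

# regroup an ((P*npix) x C) node into ((P*ncaps) x d) capsule rows
.caps_regroup <- function(node, npix, P, C, capsDim) {
  G <- C %/% capsDim
  ncaps <- npix * G
  R <- P * ncaps
  rr <- seq_len(R)
  p <- (rr - 1L) %/% ncaps
  cwithin <- (rr - 1L) %% ncaps
  pix <- cwithin %/% G
  grpi <- cwithin %% G
  srcrow <- p * npix + pix + 1L
  ij <- cbind(rep(srcrow, capsDim),
              rep(grpi, capsDim) * capsDim + rep(seq_len(capsDim), each = R))
  ag_gather2(node, ij, R, capsDim)
}

# average-pool grouping vector for a stack of P (h x w) maps, factor `pool`
.pool_groups <- function(h, w, pool, P) {
  ho <- h %/% pool; wo <- w %/% pool
  py <- rep(seq_len(h), times = w)
  px <- rep(seq_len(w), each = h)
  g <- ((px - 1L) %/% pool) * ho + ((py - 1L) %/% pool) + 1L
  as.vector(outer(g, (seq_len(P) - 1L) * ho * wo, "+"))
}

#' Capsule predictions
#'
#' Each input capsule predicts every output capsule through its own weight
#' matrix: \eqn{U_i = u_i W^{(i)}}, with \eqn{W^{(i)}} of shape
#' \code{d x (nOut * dOut)} (one map per input capsule, reshaped).
#'
#' @param u \code{n x d} matrix of (activated) input capsules.
#' @param W \code{n x d x (nOut * dOut)} array of prediction weights, third
#'   axis ordered with the output-capsule dimension fastest.
#' @param nOut,dOut output capsule count and dimension.
#' @return \code{n x nOut x dOut} array of predictions.
#' @export
predictCapsules <- function(u, W, nOut, dOut) {
  stopifnot(dim(W)[1] == nrow(u), dim(W)[2] == ncol(u),
            dim(W)[3] == nOut * dOut)
  tp <- ag_tape()
  Uf <- ag_val(ag_bmm(ag_const(tp, u), ag_const(tp, W), nrow(u)))
  aperm(array(t(Uf), c(dOut, nOut, nrow(u))), c(3, 2, 1))
}

#' Self-attention coupling coefficients
#'
#' For each output capsule j the agreement logit of input capsule i is the
#' summed inner product of its prediction with all predictions for j,
#' \eqn{a_{ij} = \sum_{i'} \langle U_{ij}, U_{i'j}\rangle / \sqrt{d^l}} (the
#' row sums of the per-output-capsule Gram matrix), followed by a softmax
#' over the output-capsule axis, so each row of C sums to 1.
#'
#' @param U \code{n x nOut x dOut} prediction array.
#' @param dl dimension of the input-layer capsules (the softmax temperature
#'   scale).
#' @return \code{n x nOut} coupling matrix; rows sum to 1.
#' @export
couplingCoefficients <- function(U, dl) {
  stopifnot(dl > 0)
  n <- dim(U)[1]; nOut <- dim(U)[2]
  Tj <- apply(U, c(2, 3), sum)                       # nOut x dOut
  a <- matrix(0, n, nOut)
  for (j in seq_len(nOut)) a[, j] <- U[, j, ] %*% Tj[j, ] / sqrt(dl)
  e <- exp(a - apply(a, 1, max))
  e / rowSums(e)
}

#' Route capsule predictions to the next layer
#'
#' \eqn{s'_j = \sum_i (C_{ij} + B_{ij})\, U_{ij}}: the contraction of the
#' predictions with the routing weights (coupling coefficients plus learned
#' log priors). Returns the pre-activation capsules; apply
#' \code{\link{squash}} for the activated next layer.
#'
#' @param U \code{n x nOut x dOut} prediction array.
#' @param C \code{n x nOut} coupling coefficients.
#' @param B \code{n x nOut} log priors (zeros at initialisation).
#' @param activate apply \code{\link{squash}} to the result.
#' @return \code{nOut x dOut} matrix of next-layer capsules.
#' @export
routeCapsules <- function(U, C, B = matrix(0, dim(U)[1], dim(U)[2]),
                          activate = FALSE) {
  n <- dim(U)[1]; nOut <- dim(U)[2]; dOut <- dim(U)[3]
  stopifnot(all(dim(C) == c(n, nOut)), all(dim(B) == c(n, nOut)))
  s <- matrix(0, nOut, dOut)
  W <- C + B
  for (j in seq_len(nOut))
    s[j, ] <- colSums(matrix(U[, j, ], n, dOut) * W[, j])
  if (activate) squash(s) else s
}

#' Full capsule routing stage
#'
#' Predictions, coupling, routing and squash in one call.
#'
#' @inheritParams predictCapsules
#' @param B \code{n x nOut} log priors.
#' @return \code{nOut x dOut} matrix of activated output capsules.
#' @export
capsuleStage <- function(u, W, nOut, dOut, B = matrix(0, nrow(u), nOut)) {
  U <- predictCapsules(u, W, nOut, dOut)
  C <- couplingCoefficients(U, dl = ncol(u))
  squash(routeCapsules(U, C, B))
}

# ---- tape version of the routing stage (batched over patches) --------------
# u: ((P*ncaps) x d) node, patch-major capsule-fast. Returns (P x nOut*dOut).
.caps_route <- function(tape, u, pget, prefix, P, ncaps, capsDim, nOut, dOut) {
  u <- ag_squash_rows(u)
  Uf <- ag_bmm(u, pget(paste0(prefix, ".Wroute")), ncaps)   # (P*n) x (nOut*dOut)
  patchof <- rep(seq_len(P), each = ncaps)
  Tj <- ag_rows(ag_rowsum_groups(Uf, patchof, P), patchof)  # sum_i' U, expanded
  # sum over dOut within each output capsule j (third-axis order: j fast? no:
  # columns ordered (j-1)*dOut + dd, dd fast)
  Gsum <- matrix(0, nOut * dOut, nOut)
  for (j in seq_len(nOut)) Gsum[(j - 1L) * dOut + seq_len(dOut), j] <- 1
  a <- ag_scale(ag_matmul(ag_mul(Uf, Tj), ag_const(tape, Gsum)),
                1 / sqrt(capsDim))                          # (P*n) x nOut
  C <- ag_softmax_rows(a)
  Bexp <- ag_rows(pget(paste0(prefix, ".B")),
                  rep(seq_len(ncaps), times = P))
  coef <- ag_matmul(ag_add(C, Bexp), ag_const(tape, t(Gsum)))
  s <- ag_rowsum_groups(ag_mul(coef, Uf), patchof, P)       # P x (nOut*dOut)
  # squash each output capsule: regroup rows to (P*nOut) x dOut and back
  R <- P * nOut
  rr <- seq_len(R)
  srcrow <- (rr - 1L) %/% nOut + 1L
  jj <- (rr - 1L) %% nOut
  ij <- cbind(rep(srcrow, dOut),
              rep(jj, dOut) * dOut + rep(seq_len(dOut), each = R))
  caps <- ag_squash_rows(ag_gather2(s, ij, R, dOut))
  # back to (P x nOut*dOut): source row (p-1)*nOut + j, source column dd
  tgt <- expand.grid(p = seq_len(P), col = seq_len(nOut * dOut))
  j <- (tgt$col - 1L) %/% dOut + 1L
  dd <- (tgt$col - 1L) %% dOut + 1L
  ij2 <- cbind((tgt$p - 1L) * nOut + j, dd)
  ag_gather2(caps, ij2, P, nOut * dOut)
}
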