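# Fusion of capsule-derived patch features with learned array-coordinate
# position embeddings, and a pre-norm transformer encoder over all spots of a
# section (one token per spot), so that every spot attends to every other.

#' Initialise position-embedding tables
#'
#' Learned lookup tables over the integer array coordinates; equal
#' coordinates always map to identical embeddings.
#'
#' @param maxX,maxY largest array coordinate to be embedded.
#' @param d embedding dimension per axis.
#' @param seed optional RNG seed.
#' @return list with \code{Ex} ((maxX+1) x d) and \code{Ey} ((maxY+1) x d).
#' @export
positionEmbedding <- function(maxX, maxY, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(Ex = matrix(stats::rnorm((maxX + 1) * d, sd = 0.1), maxX + 1, d),
       Ey = matrix(stats::rnorm((maxY + 1) * d, sd = 0.1), maxY + 1, d))
}

#' Embed spot array coordinates
#'
#' Per spot, the concatenation of \code{Ex[array_x]} and \code{Ey[array_y]}.
#'
#' @param spots a \linkS4class{SpotTable} or its data.frame.
#' @param tables from \code{\link{positionEmbedding}}.
#' @return N x 2d matrix.
#' @export
embedPositions <- function(spots, tables) {
  df <- if (is(spots, "SpotTable")) spotTable(spots) else spots
  if (max(df$array_x) + 1 > nrow(tables$Ex) ||
      max(df$array_y) + 1 > nrow(tables$Ey))
    stop("array coordinate exceeds the embedding table size")
  cbind(tables$Ex[df$array_x + 1L, , drop = FALSE],
        tables$Ey[df$array_y + 1L, , drop = FALSE])
}

#' Fuse visual features with position embeddings
#'
#' Per-spot concatenation of the capsule features and the position
#' embeddings, followed by a linear map to the model dimension.
#'
#' @param sCaps N x dF capsule features.
#' @param pos N x 2d position embeddings.
#' @param Wf (dF + 2d) x dModel fusion weights.
#' @param bf 1 x dModel bias.
#' @return N x dModel fused token sequence.
#' @export
fuseFeatures <- function(sCaps, pos, Wf, bf = matrix(0, 1, ncol(Wf))) {
  if (nrow(sCaps) != nrow(pos)) stop("sCaps and pos must have equal row counts")
  sweep(cbind(sCaps, pos) %*% Wf, 2, as.vector(bf), "+")
}

#' Initialise multi-head attention parameters
#'
#' @param dModel model (token) dimension; must be divisible by \code{m}.
#' @param m head count.
#' @param seed optional RNG seed.
#' @return list with \code{Wq}, \code{Wk}, \code{Wv}, \code{Wh} (all
#'   dModel x dModel), \code{m} and \code{dk = dModel / m}.
#' @export
attentionParams <- function(dModel, m, seed = NULL) {
  if (dModel %% m != 0) stop("dModel must be divisible by the head count")
  if (!is.null(seed)) set.seed(seed)
  ini <- function() matrix(stats::rnorm(dModel^2, sd = sqrt(1 / dModel)),
                           dModel, dModel)
  list(Wq = ini(), Wk = ini(), Wv = ini(), Wh = ini(), m = m, dk = dModel %/% m)
}

# tape version; X node (N x dModel). Returns list(out, attn = list of numeric
# per-head attention matrices captured at forward time).
.mha <- function(tape, X, Wq, Wk, Wv, Wh, m) {
  dModel <- ncol(X$val)
  dk <- dModel %/% m
  Q <- ag_matmul(X, Wq); K <- ag_matmul(X, Wk); V <- ag_matmul(X, Wv)
  heads <- vector("list", m); attn <- vector("list", m)
  for (i in seq_len(m)) {
    a <- (i - 1L) * dk + 1L; b <- i * dk
    Qh <- ag_slice_cols(Q, a, b); Kh <- ag_slice_cols(K, a, b)
    Vh <- ag_slice_cols(V, a, b)
    P <- ag_softmax_rows(ag_scale(ag_matmul(Qh, ag_t(Kh)), 1 / sqrt(dk)))
    attn[[i]] <- ag_val(P)
    heads[[i]] <- ag_matmul(P, Vh)
  }
  conc <- if (m == 1L) heads[[1]] else do.call(ag_cbind, heads)
  list(out = ag_matmul(conc, Wh), attn = attn)
}

#' Multi-head self-attention over a spot sequence
#'
#' Per head, \eqn{\mathrm{softmax}(Q K^T / \sqrt{d_k})\,V} with Q, K, V linear
#' projections of the tokens; heads are concatenated and merged. Every
#' attention row is a probability distribution over the section's spots.
#'
#' @param X N x dModel token matrix (one token per spot).
#' @param params from \code{\link{attentionParams}}.
#' @param returnAttention also return the per-head attention matrices.
#' @return N x dModel matrix, or a list \code{(out, attention)} when
#'   \code{returnAttention}.
#' @export
multiHeadAttention <- function(X, params, returnAttention = FALSE) {
  tp <- ag_tape()
  r <- .mha(tp, ag_const(tp, X), ag_const(tp, params$Wq),
            ag_const(tp, params$Wk), ag_const(tp, params$Wv),
            ag_const(tp, params$Wh), params$m)
  if (returnAttention) list(out = ag_val(r$out), attention = r$attn)
  else ag_val(r$out)
}

# one pre-norm transformer block on the tape
.vit_block <- function(tape, X, pget, prefix, m) {
  h <- ag_layernorm_rows(X, pget(paste0(prefix, ".ln1g")),
                         pget(paste0(prefix, ".ln1b")))
  att <- .mha(tape, h, pget(paste0(prefix, ".Wq")), pget(paste0(prefix, ".Wk")),
              pget(paste0(prefix, ".Wv")), pget(paste0(prefix, ".Wh")), m)
  X <- ag_add(X, att$out)
  h <- ag_layernorm_rows(X, pget(paste0(prefix, ".ln2g")),
                         pget(paste0(prefix, ".ln2b")))
  ff <- ag_matmul(ag_gelu(ag_addbias(ag_matmul(h, pget(paste0(prefix, ".Wf1"))),
                                     pget(paste0(prefix, ".bf1")))),
                  pget(paste0(prefix, ".Wf2")))
  ff <- ag_addbias(ff, pget(paste0(prefix, ".bf2")))
  ag_add(X, ff)
}

.vit_block_params <- function(dModel, expansion = 4L) {
  ini <- function(a, b, sd) matrix(stats::rnorm(a * b, sd = sd), a, b)
  list(ln1g = matrix(1, 1, dModel), ln1b = matrix(0, 1, dModel),
       Wq = ini(dModel, dModel, sqrt(1 / dModel)),
       Wk = ini(dModel, dModel, sqrt(1 / dModel)),
       Wv = ini(dModel, dModel, sqrt(1 / dModel)),
       Wh = ini(dModel, dModel, sqrt(1 / dModel)),
       ln2g = matrix(1, 1, dModel), ln2b = matrix(0, 1, dModel),
       Wf1 = ini(dModel, expansion * dModel, sqrt(1 / dModel)),
       bf1 = matrix(0, 1, expansion * dModel),
       Wf2 = ini(expansion * dModel, dModel, sqrt(1 / (expansion * dModel))),
       bf2 = matrix(0, 1, dModel))
}

#' Transformer encoder over a fused spot sequence
#'
#' \code{depth} pre-norm blocks of multi-head self-attention plus a GELU
#' feed-forward (expansion 4), both residual. Deterministic given parameters
#' and input; with all projection weights zero it reduces to the identity map
#' through the residual paths.
#'
#' @param seq N x dModel fused sequence.
#' @param params list of per-block parameter lists (see
#'   \code{\link{vitParams}}).
#' @param heads head count.
#' @return N x dModel encoded sequence.
#' @export
vitEncode <- function(seq, params, heads) {
  if (length(params) < 1L) stop("depth must be at least 1")
  tp <- ag_tape()
  X <- ag_const(tp, seq)
  for (l in seq_along(params)) {
    flat <- params[[l]]
    pget <- function(name) ag_const(tp, flat[[sub("^blk\\.", "", name)]])
    X <- .vit_block(tp, X, pget, "blk", heads)
  }
  ag_val(X)
}

#' Initialise a transformer encoder
#'
#' @param dModel token dimension.
#' @param depth number of blocks (>= 1).
#' @param seed optional RNG seed.
#' @return list of \code{depth} block-parameter lists.
#' @export
vitParams <- function(dModel, depth, seed = NULL) {
  if (depth < 1L) stop("depth must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(depth), function(l) .vit_block_params(dModel))
}
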