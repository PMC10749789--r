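# Omni-dimensional dynamic convolution: a convolution whose effective kernel
# is an attention-weighted mixture over n candidate kernels, with further
# multiplicative attention over the kernel's spatial footprint, input channels
# and output channels. All four attention branches are computed per input
# sample from a global-average-pooled descriptor.
#
# Images/feature maps are held as ((npatch * h * w) x channels) matrices with
# pixel index column-major within each patch; convolution is im2col + matmul
# with stride 1 and zero ("same") padding.

.od_init <- function(cIn, cOut, k, n, squeezeMin = 8L) {
  r <- max(squeezeMin, cIn %/% 4L)
  k2 <- k * k
  tot <- n + k2 + cIn + cOut
  p <- list()
  for (i in seq_len(n))
    p[[paste0("W", i)]] <- matrix(stats::rnorm(k2 * cIn * cOut,
                                               sd = sqrt(2 / (k2 * cIn))),
                                  k2 * cIn, cOut)
  p$bias <- matrix(0, 1, cOut)
  p$Ws <- matrix(stats::rnorm(cIn * r, sd = sqrt(2 / cIn)), cIn, r)
  p$bs <- matrix(0, 1, r)
  p$Wh <- matrix(stats::rnorm(r * tot, sd = sqrt(1 / r)), r, tot)
  p$bh <- matrix(0, 1, tot)
  p$dims <- list(cIn = cIn, cOut = cOut, k = k, n = n, r = r)
  p
}

#' Initialise parameters of an omni-dimensional dynamic convolution layer
#'
#' @param cIn,cOut input / output channel counts.
#' @param kernelSize odd spatial kernel size k.
#' @param nKernels number of candidate kernels n.
#' @param seed optional RNG seed for reproducible initialisation.
#' @return a parameter list: candidate kernels \code{W1..Wn} (each
#'   \code{(k^2 cIn) x cOut}), \code{bias}, squeeze FC \code{Ws}/\code{bs},
#'   attention-head FC \code{Wh}/\code{bh} and a \code{dims} record.
#' @export
odconvParams <- function(cIn, cOut, kernelSize = 3L, nKernels = 4L, seed = NULL) {
  if (kernelSize %% 2L != 1L) stop("kernel size must be odd")
  if (nKernels < 1L) stop("need at least one kernel")
  if (!is.null(seed)) set.seed(seed)
  .od_init(cIn, cOut, kernelSize, nKernels)
}

# expansion matrices mapping per-offset / per-channel attentions onto the
# im2col column layout (offset fast, channel slow)
.od_expand <- function(k2, cIn) {
  Ek <- matrix(0, k2, k2 * cIn)
  Ec <- matrix(0, cIn, k2 * cIn)
  for (ch in seq_len(cIn)) {
    cols <- (ch - 1L) * k2 + seq_len(k2)
    Ek[cbind(seq_len(k2), cols)] <- 1
    Ec[ch, cols] <- 1
  }
  list(Ek = Ek, Ec = Ec)
}

# attention branch on the tape; gap is a (P x cIn) node. Returns nodes
# aw (P x n), akv (P x k2), ac (P x cIn), ao (P x cOut).
.od_attention <- function(tape, gap, pget, prefix, dims,
                          kernelAttention = "sigmoid") {
  with(dims, {
    z <- ag_relu(ag_addbias(ag_matmul(gap, pget(paste0(prefix, ".Ws"))),
                            pget(paste0(prefix, ".bs"))))
    a <- ag_addbias(ag_matmul(z, pget(paste0(prefix, ".Wh"))),
                    pget(paste0(prefix, ".bh")))
    k2 <- k * k
    aw <- ag_slice_cols(a, 1L, n)
    aw <- if (kernelAttention == "softmax") ag_softmax_rows(aw) else ag_sigmoid(aw)
    list(aw = aw,
         akv = ag_sigmoid(ag_slice_cols(a, n + 1L, n + k2)),
         ac = ag_sigmoid(ag_slice_cols(a, n + k2 + 1L, n + k2 + cIn)),
         ao = ag_sigmoid(ag_slice_cols(a, n + k2 + cIn + 1L, n + k2 + cIn + cOut)))
  })
}

# expansion matrices mapping a per-kernel-row (K = k2*cIn) or per-output-
# channel attention onto the column-major-vectorised (K x cOut) kernel layout
.od_expand_kernel <- function(K, cOut) {
  Es <- matrix(0, K, K * cOut)
  Eo <- matrix(0, cOut, K * cOut)
  for (co in seq_len(cOut)) {
    cols <- (co - 1L) * K + seq_len(K)
    Es[cbind(seq_len(K), cols)] <- 1
    Eo[co, cols] <- 1
  }
  list(Es = Es, Eo = Eo)
}

# full ODConv layer on the tape. x: ((P*h*w) x cIn) node.
# The effective kernel of each patch is assembled in kernel space (the
# attention mixes and rescales the (K x cOut) kernels, which are tiny) and
# applied by a per-patch matmul of the im2col'd pixels.
# attOverride: optional list of numeric matrices (aw P x n, akv P x k2,
# ac P x cIn, ao P x cOut) replacing the learned attention branch.
# mode "omni" uses all four attentions; "kernel_only" uses only aw (the
# plain dynamic-convolution degenerate case).
# cache: optional environment memoising index/expansion matrices; xcPre:
# optional precomputed im2col matrix when x is constant (training input).
.od_layer <- function(tape, x, pget, prefix, dims, h, w, P,
                      kernelAttention = "sigmoid", mode = "omni",
                      attOverride = NULL, cache = NULL, xcPre = NULL) {
  k <- dims$k; n <- dims$n; cIn <- dims$cIn; cOut <- dims$cOut
  k2 <- k * k
  K <- k2 * cIn
  memo <- function(key, fn) {
    if (is.null(cache)) return(fn())
    if (is.null(cache[[key]])) cache[[key]] <- fn()
    cache[[key]]
  }
  att <- if (is.null(attOverride)) {
    gap <- ag_rowsum_groups(x, rep(seq_len(P), each = h * w), P, average = TRUE)
    .od_attention(tape, gap, pget, prefix, dims, kernelAttention)
  } else {
    lapply(attOverride, function(m) ag_const(tape, m))
  }
  xc <- if (!is.null(xcPre)) ag_const(tape, xcPre)
        else ag_im2col(x, memo(sprintf("idx.%d.%d.%d.%d", h, w, k, P),
                               function() im2col_index(h, w, k, P)))
  Wall <- do.call(ag_rbind, lapply(seq_len(n), function(i)
    ag_reshape(pget(paste0(prefix, ".W", i)), 1L, K * cOut)))
  Weff <- ag_matmul(att$aw, Wall)                  # P x (K*cOut)
  if (mode == "omni") {
    ex <- memo(sprintf("odex.%d.%d", k2, cIn), function() .od_expand(k2, cIn))
    ek <- memo(sprintf("odek.%d.%d", K, cOut),
               function() .od_expand_kernel(K, cOut))
    S <- ag_mul(ag_matmul(att$akv, ag_const(tape, ex$Ek)),
                ag_matmul(att$ac, ag_const(tape, ex$Ec)))   # P x K
    Weff <- ag_mul(Weff, ag_matmul(S, ag_const(tape, ek$Es)))
    Weff <- ag_mul(Weff, ag_matmul(att$ao, ag_const(tape, ek$Eo)))
  }
  out <- ag_patch_matmul(xc, Weff, P, K, cOut)
  ag_addbias(out, pget(paste0(prefix, ".bias")))
}

# numeric helpers: single-sample array <-> pixel-major matrix
.chw_to_mat <- function(x) {
  d <- dim(x)                           # c x h x w
  t(matrix(x, d[1], d[2] * d[3]))       # (h*w) x c, pixel column-major
}

.mat_to_chw <- function(m, h, w) {
  aperm(array(m, c(h, w, ncol(m))), c(3, 1, 2))
}

# wrap a plain parameter list as constant leaves with a prefix
.const_pget <- function(tape, params, prefix) {
  function(name) {
    key <- sub(paste0("^", prefix, "\\."), "", name)
    ag_const(tape, params[[key]])
  }
}

#' Attention branch of an ODConv layer
#'
#' Global-average-pools the input over space, applies the squeeze FC with
#' ReLU, then four parallel head FCs with a sigmoid each (the kernel-wise
#' head can optionally be softmax-normalised).
#'
#' @param x input feature map, \code{cIn x h x w} array.
#' @param params parameter list from \code{\link{odconvParams}}.
#' @param kernelAttention \code{"sigmoid"} (default) or \code{"softmax"} for
#'   the kernel-selection head.
#' @return list with \code{alpha_w} (length n), \code{alpha_k} (k x k),
#'   \code{alpha_c} (length cIn), \code{alpha_o} (length cOut); sigmoid
#'   entries lie strictly inside (0, 1).
#' @export
attentionBranch <- function(x, params, kernelAttention = c("sigmoid", "softmax")) {
  kernelAttention <- match.arg(kernelAttention)
  dims <- params$dims
  if (dim(x)[1] != dims$cIn) stop("input channel count does not match params")
  tp <- ag_tape()
  gap <- ag_const(tp, matrix(colMeans(.chw_to_mat(x)), 1))
  att <- .od_attention(tp, gap, .const_pget(tp, params, "od"), "od", dims,
                       kernelAttention)
  list(alpha_w = as.vector(ag_val(att$aw)),
       alpha_k = matrix(ag_val(att$akv), dims$k, dims$k),
       alpha_c = as.vector(ag_val(att$ac)),
       alpha_o = as.vector(ag_val(att$ao)))
}

#' Omni-dimensional dynamic convolution forward pass
#'
#' Computes attention over the four kernel dimensions from the input itself
#' (or uses the supplied attention), forms the effective kernel
#' \eqn{\sum_i \alpha_{wi} (\alpha_{ki} \odot \alpha_{ci} \odot \alpha_{oi}
#' \odot W_i)} and convolves (stride 1, zero padding).
#'
#' @param x input, \code{cIn x h x w} array.
#' @param params from \code{\link{odconvParams}}.
#' @param attention optional list as returned by \code{\link{attentionBranch}}
#'   (overrides the computed attention; handy for controlled experiments).
#' @param mode \code{"omni"} (all four attentions) or \code{"kernel_only"}
#'   (only the kernel-mixture attention of the plain dynamic convolution).
#' @param kernelAttention see \code{\link{attentionBranch}}.
#' @return \code{cOut x h x w} array.
#' @export
odconvForward <- function(x, params, attention = NULL,
                          mode = c("omni", "kernel_only"),
                          kernelAttention = c("sigmoid", "softmax")) {
  mode <- match.arg(mode); kernelAttention <- match.arg(kernelAttention)
  dims <- params$dims
  d <- dim(x)
  if (d[1] != dims$cIn) stop("input channel count does not match params")
  h <- d[2]; w <- d[3]
  tp <- ag_tape()
  xn <- ag_const(tp, .chw_to_mat(x))
  ov <- NULL
  if (!is.null(attention))
    ov <- list(aw = matrix(attention$alpha_w, 1),
               akv = matrix(as.vector(attention$alpha_k), 1),
               ac = matrix(attention$alpha_c, 1),
               ao = matrix(attention$alpha_o, 1))
  out <- .od_layer(tp, xn, .const_pget(tp, params, "od"), "od", dims,
                   h, w, 1L, kernelAttention, mode, attOverride = ov)
  .mat_to_chw(ag_val(out), h, w)
}

#' Plain dynamic convolution (kernel-wise attention only)
#'
#' The degenerate mode of \code{\link{odconvForward}} in which only the
#' kernel-mixture coefficients act: \eqn{Y = (\sum_i \alpha_{wi} W_i) * X}.
#' Provided for ablation.
#'
#' @inheritParams odconvForward
#' @return \code{cOut x h x w} array.
#' @export
dynamicConvForward <- function(x, params, attention = NULL,
                               kernelAttention = c("sigmoid", "softmax")) {
  odconvForward(x, params, attention = attention, mode = "kernel_only",
                kernelAttention = match.arg(kernelAttention))
}
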