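# Reverse-mode autodiff core.
#
# The network modules in this package (dynamic convolution, capsule routing,
# transformer encoder, graph attention) are differentiated with a small
# tape-based reverse-mode engine. Values are plain numeric matrices; a forward
# pass records nodes on a tape, and ag_backward() sweeps the tape in reverse
# topological (= creation) order. Gradients flow only into subgraphs that
# contain parameters (`ng` flag), so large constant inputs such as im2col'd
# pixel blocks cost nothing on the way back.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, val, parents = list(), backfn = NULL, ng = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$ng <- if (is.null(ng)) any(vapply(parents, function(p) p$ng, logical(1))) else ng
  nd$taperef <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  class(nd) <- "agnode"
  nd
}

ag_const <- function(tape, x) ag_node(tape, x, ng = FALSE)

ag_param <- function(tape, x, name) {
  nd <- ag_node(tape, x, ng = TRUE)
  nd$pname <- name
  nd
}

ag_val <- function(nd) nd$val

#' @noRd
ag_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  stopifnot(length(root$val) == 1L)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backfn)) next
    pg <- nd$backfn(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$ng || is.null(pg[[k]])) next
      grads[[p$id]] <- if (is.null(grads[[p$id]])) pg[[k]] else grads[[p$id]] + pg[[k]]
    }
  }
  grads
}

# Collect gradients of named parameter leaves after a backward sweep.
ag_param_grads <- function(tape, grads) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$pname)) {
      g <- grads[[nd$id]]
      if (is.null(g)) g <- array(0, dim(nd$val))
      if (!is.null(out[[nd$pname]])) g <- g + out[[nd$pname]]
      out[[nd$pname]] <- g
    }
  }
  out
}

## ---- arithmetic -----------------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a_tape(a, b), a$val %*% b$val, list(a, b), function(g) {
    list(if (a$ng) g %*% t(b$val) else NULL,
         if (b$ng) crossprod(a$val, g) else NULL)
  })
}

a_tape <- function(...) {
  for (nd in list(...)) if (!is.null(nd$taperef)) return(nd$taperef)
  stop("internal: no tape reference on nodes")
}

ag_add <- function(a, b) {
  ag_node(a_tape(a, b), a$val + b$val, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a_tape(a, b), a$val - b$val, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  ag_node(a_tape(a, b), a$val * b$val, list(a, b), function(g) {
    list(if (a$ng) g * b$val else NULL, if (b$ng) g * a$val else NULL)
  })
}

# add a 1 x k bias row to every row of a (n x k)
ag_addbias <- function(a, b) {
  ag_node(a_tape(a, b), sweep(a$val, 2L, as.vector(b$val), "+"), list(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ag_scale <- function(a, s) {
  ag_node(a_tape(a), a$val * s, list(a), function(g) list(g * s))
}

# scale row i of a by v[i]  (v: n x 1 node)
ag_rowmul <- function(a, v) {
  vv <- as.vector(v$val)
  ag_node(a_tape(a, v), a$val * vv, list(a, v), function(g) {
    list(if (a$ng) g * vv else NULL,
         if (v$ng) matrix(rowSums(g * a$val), ncol = 1L) else NULL)
  })
}

# scale column j of a by v[j]  (v: 1 x m node)
ag_colmul <- function(a, v) {
  vv <- as.vector(v$val)
  ag_node(a_tape(a, v), sweep(a$val, 2L, vv, "*"), list(a, v), function(g) {
    list(if (a$ng) sweep(g, 2L, vv, "*") else NULL,
         if (v$ng) matrix(colSums(g * a$val), 1L) else NULL)
  })
}

## ---- nonlinearities -------------------------------------------------------

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ag_node(a_tape(a), s, list(a), function(g) list(g * s * (1 - s)))
}

ag_relu <- function(a) {
  m <- a$val > 0
  ag_node(a_tape(a), a$val * m, list(a), function(g) list(g * m))
}

ag_leakyrelu <- function(a, slope = 0.2) {
  d <- ifelse(a$val > 0, 1, slope)
  ag_node(a_tape(a), a$val * d, list(a), function(g) list(g * d))
}

ag_elu <- function(a) {
  v <- ifelse(a$val > 0, a$val, exp(pmin(a$val, 0)) - 1)
  d <- ifelse(a$val > 0, 1, v + 1)
  ag_node(a_tape(a), v, list(a), function(g) list(g * d))
}

ag_gelu <- function(a) {
  x <- a$val
  ag_node(a_tape(a), x * pnorm(x), list(a),
          function(g) list(g * (pnorm(x) + x * dnorm(x))))
}

# row-wise softmax
ag_softmax_rows <- function(a) {
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ag_node(a_tape(a), p, list(a), function(g) list(p * (g - rowSums(g * p))))
}

# capsule squash applied to each row: u = (1 - exp(-||s||)) s / ||s||
ag_squash_rows <- function(a) {
  s <- a$val
  r <- sqrt(rowSums(s^2))
  small <- r < 1e-8
  f <- ifelse(small, 1 - r / 2, (1 - exp(-r)) / pmax(r, 1e-12))
  u <- s * f
  ag_node(a_tape(a), u, list(a), function(g) {
    fp <- ifelse(small, -0.5 + r / 3,
                 (exp(-r) * r - (1 - exp(-r))) / pmax(r, 1e-12)^2)
    sg <- rowSums(s * g)
    list(g * f + s * (fp * sg / pmax(r, 1e-8)))
  })
}

## ---- shape ops ------------------------------------------------------------

ag_t <- function(a) ag_node(a_tape(a), t(a$val), list(a), function(g) list(t(g)))

# gather rows by integer index (repeats allowed; backward scatter-adds)
ag_rows <- function(a, idx) {
  ag_node(a_tape(a), a$val[idx, , drop = FALSE], list(a), function(g) {
    rs <- rowsum(g, idx)
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    ga[as.integer(rownames(rs)), ] <- rs
    list(ga)
  })
}

ag_slice_cols <- function(a, from, to) {
  ag_node(a_tape(a), a$val[, from:to, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    ga[, from:to] <- g
    list(ga)
  })
}

ag_cbind <- function(...) {
  ps <- list(...)
  w <- vapply(ps, function(p) ncol(p$val), integer(1))
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(a_tape(ps[[1]]), do.call(cbind, lapply(ps, ag_val)), ps, function(g) {
    lapply(seq_along(ps), function(k) {
      if (ps[[k]]$ng) g[, starts[k]:ends[k], drop = FALSE] else NULL
    })
  })
}

ag_rbind <- function(...) {
  ps <- list(...)
  hts <- vapply(ps, function(p) nrow(p$val), integer(1))
  ends <- cumsum(hts)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(a_tape(ps[[1]]), do.call(rbind, lapply(ps, ag_val)), ps, function(g) {
    lapply(seq_along(ps), function(k) {
      if (ps[[k]]$ng) g[starts[k]:ends[k], , drop = FALSE] else NULL
    })
  })
}

# per-patch matmul: x ((P*hw) x K) in patch-major blocks, W (P x (K*cout))
# holding one column-major-vectorised (K x cout) kernel per row;
# out rows of patch p = x_p %*% W_p.
ag_patch_matmul <- function(x, W, P, K, cout) {
  R <- nrow(x$val); hw <- R %/% P
  out <- matrix(0, R, cout)
  for (p in seq_len(P)) {
    rows <- (p - 1L) * hw + seq_len(hw)
    out[rows, ] <- x$val[rows, , drop = FALSE] %*%
      matrix(W$val[p, ], K, cout)
  }
  ag_node(a_tape(x, W), out, list(x, W), function(g) {
    gx <- if (x$ng) matrix(0, R, K) else NULL
    gW <- if (W$ng) matrix(0, P, K * cout) else NULL
    for (p in seq_len(P)) {
      rows <- (p - 1L) * hw + seq_len(hw)
      gp <- g[rows, , drop = FALSE]
      Wp <- matrix(W$val[p, ], K, cout)
      if (!is.null(gx)) gx[rows, ] <- gp %*% t(Wp)
      if (!is.null(gW))
        gW[p, ] <- as.vector(crossprod(x$val[rows, , drop = FALSE], gp))
    }
    list(gx, gW)
  })
}

# column-major reshape (a pure relabelling of entries)
ag_reshape <- function(a, nr, nc) {
  v <- a$val
  dim(v) <- c(nr, nc)
  onr <- nrow(a$val); onc <- ncol(a$val)
  ag_node(a_tape(a), v, list(a), function(g) {
    dim(g) <- c(onr, onc)
    list(g)
  })
}

# arbitrary element gather: out[r, c] = a[ij[k, 1], ij[k, 2]] with k the
# column-major index of (r, c). Source cells must be distinct (bijective
# relabelling, as in capsule regrouping); backward assigns, not accumulates.
ag_gather2 <- function(a, ij, nr, nc) {
  v <- matrix(a$val[ij], nr, nc)
  ag_node(a_tape(a), v, list(a), function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    ga[ij] <- as.vector(g)
    list(ga)
  })
}

# group rows and sum (or average) within groups; groups must cover 1..ngroups
ag_rowsum_groups <- function(a, groups, ngroups, average = FALSE) {
  cnt <- tabulate(groups, nbins = ngroups)
  v <- rowsum(a$val, groups)
  if (average) v <- v / cnt
  ag_node(a_tape(a), v, list(a), function(g) {
    if (average) g <- g / cnt
    list(g[groups, , drop = FALSE])
  })
}

## ---- structured ops -------------------------------------------------------

# Index table for stride-1 same-padding im2col over a stack of images held as
# a ((npatch*h*w) x c) matrix, pixel index column-major within each image.
# Entry [t, o] is the source row feeding output pixel t at kernel offset o,
# or 0 for zero padding.
im2col_index <- function(h, w, k, npatch = 1L) {
  half <- (k - 1L) %/% 2L
  off <- expand.grid(dy = -half:(k - 1L - half), dx = -half:(k - 1L - half))
  py <- rep(seq_len(h), times = w)
  px <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k)
  for (o in seq_len(k * k)) {
    sy <- py + off$dy[o]
    sx <- px + off$dx[o]
    ok <- sy >= 1L & sy <= h & sx >= 1L & sx <= w
    idx[ok, o] <- (sx[ok] - 1L) * h + sy[ok]
  }
  if (npatch > 1L) {
    base <- idx
    idx <- matrix(0L, npatch * h * w, k * k)
    for (p in seq_len(npatch)) {
      blk <- base
      blk[blk > 0L] <- blk[blk > 0L] + (p - 1L) * h * w
      idx[(p - 1L) * h * w + seq_len(h * w), ] <- blk
    }
  }
  idx
}

# plain-numeric im2col given an index table
im2col_apply <- function(x, idx) {
  k2 <- ncol(idx)
  N <- nrow(x); cin <- ncol(x)
  xp <- rbind(matrix(0, 1L, cin), x)
  big <- xp[as.vector(idx) + 1L, , drop = FALSE]   # (N*k2) x cin
  dim(big) <- c(N, k2 * cin)
  big
}

# im2col as a differentiable op: input ((N) x c) -> (N x (k2*c)), column
# order kernel-offset-fast within channel.
ag_im2col <- function(a, idx) {
  k2 <- ncol(idx)
  N <- nrow(a$val); cin <- ncol(a$val)
  big <- im2col_apply(a$val, idx)
  ag_node(a_tape(a), big, list(a), function(g) {
    dim(g) <- c(N, k2, cin)
    ga <- matrix(0, N, cin)
    for (o in seq_len(k2)) {
      src <- idx[, o]
      ok <- src > 0L
      ga[src[ok], ] <- ga[src[ok], , drop = FALSE] + g[ok, o, ]
    }
    list(ga)
  })
}

# batched per-capsule linear maps: rows of u are capsules in patch-major,
# capsule-fast order; W is an (ncaps x d x D) array, out[r, ] = u[r, ] %*% W[i(r), , ]
ag_bmm <- function(u, W, ncaps) {
  R <- nrow(u$val); D <- dim(W$val)[3]
  sel <- lapply(seq_len(ncaps), function(i) seq.int(i, R, by = ncaps))
  out <- matrix(0, R, D)
  for (i in seq_len(ncaps))
    out[sel[[i]], ] <- u$val[sel[[i]], , drop = FALSE] %*% W$val[i, , ]
  ag_node(a_tape(u, W), out, list(u, W), function(g) {
    gu <- if (u$ng) matrix(0, R, ncol(u$val)) else NULL
    gW <- if (W$ng) array(0, dim(W$val)) else NULL
    for (i in seq_len(ncaps)) {
      gi <- g[sel[[i]], , drop = FALSE]
      if (!is.null(gu)) gu[sel[[i]], ] <- gi %*% t(W$val[i, , ])
      if (!is.null(gW)) gW[i, , ] <- crossprod(u$val[sel[[i]], , drop = FALSE], gi)
    }
    list(gu, gW)
  })
}

## ---- normalisation & losses -----------------------------------------------

ag_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  m <- ncol(x$val)
  mu <- rowMeans(x$val)
  va <- rowMeans(x$val^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat <- (x$val - mu) * inv
  gv <- as.vector(gamma$val); bv <- as.vector(beta$val)
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_node(a_tape(x, gamma), out, list(x, gamma, beta), function(g) {
    gxh <- sweep(g, 2L, gv, "*")
    gx <- inv * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
    list(if (x$ng) gx else NULL,
         if (gamma$ng) matrix(colSums(g * xhat), 1L) else NULL,
         if (beta$ng) matrix(colSums(g), 1L) else NULL)
  })
}

ag_sum <- function(a) {
  ag_node(a_tape(a), matrix(sum(a$val), 1L, 1L), list(a),
          function(g) list(matrix(g[1], nrow(a$val), ncol(a$val))))
}

ag_mse <- function(a, target) {
  d <- a$val - target
  ag_node(a_tape(a), matrix(mean(d^2), 1L, 1L), list(a),
          function(g) list(g[1] * 2 * d / length(d)))
}
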