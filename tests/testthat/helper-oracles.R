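# Independent brute-force oracles shared across the unit and acceptance
# suites. Each re-derives its quantity by direct enumeration/loops and stays
# independent of the package's vectorised implementations.

# independent pair-counting ARI oracle: classify every pair of items
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# brute-force direct convolution: x (cIn x h x w), Weff ((k2*cIn) x cOut) in
# the package's column layout (kernel offset fast within input channel; the
# offset grid is column-major over (dy, dx) with dy, dx in -half:(k-1-half))
conv_oracle <- function(x, Weff, k) {
  cIn <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  cOut <- ncol(Weff)
  half <- (k - 1) %/% 2
  off <- expand.grid(dy = -half:(k - 1 - half), dx = -half:(k - 1 - half))
  out <- array(0, c(cOut, h, w))
  for (co in seq_len(cOut)) for (y in seq_len(h)) for (xx in seq_len(w)) {
    acc <- 0
    for (ch in seq_len(cIn)) for (o in seq_len(k * k)) {
      sy <- y + off$dy[o]; sx <- xx + off$dx[o]
      if (sy >= 1 && sy <= h && sx >= 1 && sx <= w)
        acc <- acc + Weff[(ch - 1) * k * k + o, co] * x[ch, sy, sx]
    }
    out[co, y, xx] <- acc
  }
  out
}

# naive reference for the whole routing stage (loops only)
caps_loop_reference <- function(u, W, nOut, dOut, B = NULL) {
  n <- nrow(u); d <- ncol(u)
  if (is.null(B)) B <- matrix(0, n, nOut)
  U <- array(0, c(n, nOut, dOut))
  for (i in 1:n) {
    flat <- numeric(nOut * dOut)
    for (cc in seq_len(nOut * dOut))
      flat[cc] <- sum(u[i, ] * W[i, , cc])
    for (j in 1:nOut) for (dd in 1:dOut)
      U[i, j, dd] <- flat[(j - 1) * dOut + dd]
  }
  a <- matrix(0, n, nOut)
  for (i in 1:n) for (j in 1:nOut) {
    s <- 0
    for (i2 in 1:n) s <- s + sum(U[i, j, ] * U[i2, j, ])
    a[i, j] <- s / sqrt(d)
  }
  C <- matrix(0, n, nOut)
  for (i in 1:n) C[i, ] <- exp(a[i, ]) / sum(exp(a[i, ]))
  s2 <- matrix(0, nOut, dOut)
  for (j in 1:nOut) for (dd in 1:dOut)
    for (i in 1:n) s2[j, dd] <- s2[j, dd] + (C[i, j] + B[i, j]) * U[i, j, dd]
  # squash
  out <- matrix(0, nOut, dOut)
  for (j in 1:nOut) {
    r <- sqrt(sum(s2[j, ]^2))
    if (r > 0) out[j, ] <- (1 - exp(-r)) * s2[j, ] / r
  }
  out
}

# brute-force multi-head attention
mha_oracle <- function(X, p) {
  N <- nrow(X); dm <- ncol(X); dk <- dm / p$m
  conc <- NULL
  for (i in seq_len(p$m)) {
    cols <- (i - 1) * dk + 1:dk
    Q <- X %*% p$Wq[, cols]; K <- X %*% p$Wk[, cols]; V <- X %*% p$Wv[, cols]
    H <- matrix(0, N, dk)
    for (a in 1:N) {
      logits <- vapply(1:N, function(b) sum(Q[a, ] * K[b, ]) / sqrt(dk),
                       numeric(1))
      wts <- exp(logits - max(logits)); wts <- wts / sum(wts)
      for (b in 1:N) H[a, ] <- H[a, ] + wts[b] * V[b, ]
    }
    conc <- cbind(conc, H)
  }
  conc %*% p$Wh
}

knn_oracle <- function(px, py, k) {
  n <- length(px)
  D <- as.matrix(dist(cbind(px, py)))
  lapply(seq_len(n), function(i) {
    cand <- setdiff(seq_len(n), i)
    cand[order(D[i, cand], cand)][seq_len(min(k, n - 1))]
  })
}
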