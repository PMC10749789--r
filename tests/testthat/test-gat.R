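# k-NN spot graph and graph attention vs brute-force oracles.

mkxy <- function(px, py) data.frame(
  spot_id = paste0("s", seq_along(px)), section_id = "A",
  array_x = seq_along(px) - 1L, array_y = 0L, pixel_x = px, pixel_y = py)


test_that("edge distances are Euclidean", {
  g <- buildKnnGraph(mkxy(c(0, 3), c(0, 4)), k = 4)
  expect_equal(g@distances, c(5, 5))               # 3-4-5 triangle, both ways
  expect_equal(g@k, 1L)                            # capped at N - 1
})

test_that("five collinear spots with k = 4 give the complete graph", {
  g <- buildKnnGraph(mkxy(0:4, rep(0, 5)), k = 4)
  expect_equal(nrow(g@edges), 20L)
  for (i in 1:5)
    expect_setequal(g@edges[g@edges[, 1] == i, 2], setdiff(1:5, i))
})

test_that("neighbour sets match the all-pairs oracle on grids and at random", {
  px <- rep(0:2, 2); py <- rep(0:1, each = 3)      # 2 x 3 unit grid
  g <- buildKnnGraph(mkxy(px, py), k = 4)
  oracle <- knn_oracle(px, py, 4)
  for (i in seq_along(px))
    expect_identical(g@edges[g@edges[, 1] == i, 2], oracle[[i]])
  set.seed(61)
  for (trial in 1:5) {
    n <- sample(5:50, 1)
    px <- runif(n, 0, 100); py <- runif(n, 0, 100)
    g <- buildKnnGraph(mkxy(px, py), k = 4)
    oracle <- knn_oracle(px, py, 4)
    for (i in seq_len(n)) {
      expect_identical(g@edges[g@edges[, 1] == i, 2], oracle[[i]])
      expect_length(oracle[[i]], min(4L, n - 1L))  # out-degree invariant
    }
  }
})

test_that("duplicate coordinates are allowed but flagged", {
  expect_warning(buildKnnGraph(mkxy(c(0, 0, 1), c(0, 0, 0)), k = 2),
                 "zero-length")
  expect_error(buildKnnGraph(mkxy(0, 0)), "at least two")
})

test_that("edge scores follow the linear scorer", {
  set.seed(62)
  g <- buildKnnGraph(mkxy(c(0, 1, 5), c(0, 0, 0)), k = 2)
  M <- 3L
  p <- gatParams(M, seed = 63)
  h <- matrix(rnorm(3 * M), 3)
  e <- edgeScores(h, g, p)
  Hw <- h %*% p$Wh
  for (r in seq_len(nrow(g@edges))) {
    i <- g@edges[r, 1]; j <- g@edges[r, 2]
    expect_equal(e[r], sum(Hw[i, ] * p$a1) + sum(Hw[j, ] * p$a2),
                 tolerance = 1e-12)
  }
  p0 <- p; p0$a1[] <- 0; p0$a2[] <- 0
  expect_true(all(edgeScores(h, g, p0) == 0))
  hsame <- matrix(rep(rnorm(M), each = 3), 3)      # identical nodes
  expect_equal(length(unique(round(edgeScores(hsame, g, p), 10))), 1L)
})

test_that("attention normalisation softmaxes within each neighbourhood", {
  g <- buildKnnGraph(mkxy(c(0, 1, 2, 3, 10), c(0, 0, 0, 0, 0)), k = 4)
  e <- rep(1.7, nrow(g@edges))                     # equal scores
  a <- normalizeAttention(e, g)
  expect_equal(a, rep(0.25, length(e)), tolerance = 1e-12)
  # saturation
  e2 <- e; e2[1] <- 10; e2[2:4] <- -10
  a2 <- normalizeAttention(e2, g)
  expect_gt(a2[1], 0.999)
  # hand case (0, ln 2) over 2 neighbours (both scores nonnegative: the
  # LeakyReLU is inert): softmax = (1/3, 2/3)
  g2 <- buildKnnGraph(mkxy(c(0, 1, 2), c(0, 0, 0)), k = 2)
  a3 <- normalizeAttention(c(0, log(2), 0, 0, 0, 0), g2)
  expect_equal(a3[1:2], c(1 / 3, 2 / 3), tolerance = 1e-12)
  # negative scores go through the LeakyReLU before the softmax
  a4 <- normalizeAttention(c(-1, 1, 0, 0, 0, 0), g2)
  expect_equal(a4[1:2], exp(c(-0.2, 1)) / sum(exp(c(-0.2, 1))),
               tolerance = 1e-12)
  # per-node sums equal 1
  set.seed(64)
  for (i in 1:100) {
    e5 <- rnorm(nrow(g2@edges), sd = 3)
    a5 <- normalizeAttention(e5, g2)
    expect_equal(as.vector(rowsum(a5, g2@edges[, 1])), rep(1, 3),
                 tolerance = 1e-6)
  }
})

test_that("aggregation is the attention-weighted neighbour average", {
  g <- buildKnnGraph(mkxy(c(0, 1, 2), c(0, 0, 0)), k = 2)
  v <- c(3, -1)
  h <- matrix(rep(v, each = 3), 3)                 # all neighbours identical
  a <- normalizeAttention(rnorm(6), g)
  expect_equal(aggregateNeighbors(h, a, g), h, tolerance = 1e-12)
  # one-hot attention copies that neighbour
  h2 <- matrix(rnorm(6), 3)
  a2 <- rep(c(1, 0), 3)
  got <- aggregateNeighbors(h2, a2, g)
  for (i in 1:3) {
    first <- g@edges[g@edges[, 1] == i, 2][1]
    expect_equal(got[i, ], h2[first, ], tolerance = 1e-12)
  }
  # loop oracle + convex hull bounds
  set.seed(65)
  a3 <- normalizeAttention(rnorm(6), g)
  got3 <- aggregateNeighbors(h2, a3, g)
  for (i in 1:3) {
    idx <- which(g@edges[, 1] == i)
    nb <- g@edges[idx, 2]
    want <- colSums(h2[nb, , drop = FALSE] * a3[idx])
    expect_equal(got3[i, ], want, tolerance = 1e-12)
    expect_true(all(got3[i, ] <= apply(h2[nb, , drop = FALSE], 2, max) + 1e-12))
    expect_true(all(got3[i, ] >= apply(h2[nb, , drop = FALSE], 2, min) - 1e-12))
  }
})

test_that("the embedding update applies ELU(concat %*% omega + beta)", {
  p <- list(omega = matrix(0, 4, 3), beta = matrix(0, 1, 3))
  h <- matrix(rnorm(6), 3, 2); ho <- matrix(rnorm(6), 3, 2)
  expect_true(all(updateEmbedding(h, ho, p) == 0))  # ELU(0) = 0
  set.seed(66)
  p2 <- list(omega = matrix(rnorm(12), 4, 3), beta = matrix(rnorm(3), 1))
  got <- updateEmbedding(h, ho, p2)
  z <- sweep(cbind(h, ho) %*% p2$omega, 2, as.vector(p2$beta), "+")
  expect_equal(got, ifelse(z > 0, z, exp(z) - 1), tolerance = 1e-12)
  expect_equal(got[z > 0], z[z > 0])               # linear on the positive part
})

test_that("the expression head is a plain linear map", {
  set.seed(67)
  h <- matrix(rnorm(12), 3, 4)
  p <- list(Wout = matrix(rnorm(8), 4, 2), bout = matrix(c(1, -1), 1))
  expect_equal(expressionHead(h, p),
               sweep(h %*% p$Wout, 2, c(1, -1), "+"), tolerance = 1e-12)
  p0 <- list(Wout = matrix(0, 4, 1), bout = matrix(0, 1, 1))
  expect_true(all(expressionHead(h, p0) == 0))
  expect_equal(dim(expressionHead(h, p)), c(3L, 2L))
})
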