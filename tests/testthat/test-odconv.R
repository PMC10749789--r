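# Omni-dimensional dynamic convolution vs brute-force oracles.


relu_scalar <- function(z) max(z, 0)

ones_attention <- function(p) {
  d <- p$dims
  list(alpha_w = rep(1, d$n), alpha_k = matrix(1, d$k, d$k),
       alpha_c = rep(1, d$cIn), alpha_o = rep(1, d$cOut))
}

test_that("with unit attentions and n = 1 the layer is a plain convolution", {
  set.seed(31)
  p <- odconvParams(2, 3, kernelSize = 3, nKernels = 1)
  x <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  got <- odconvForward(x, p, attention = ones_attention(p))
  want <- conv_oracle(x, p$W1, 3)
  want <- sweep(want, 1, as.vector(p$bias), "+")
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("kernel attention (0.5, 0.5) convolves with the average kernel", {
  set.seed(32)
  p <- odconvParams(2, 2, kernelSize = 3, nKernels = 2)
  x <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  att <- ones_attention(p); att$alpha_w <- c(0.5, 0.5)
  got <- odconvForward(x, p, attention = att)
  want <- conv_oracle(x, (p$W1 + p$W2) / 2, 3)
  want <- sweep(want, 1, as.vector(p$bias), "+")
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the scalar 1x1 case multiplies through all four attentions", {
  p <- odconvParams(1, 1, kernelSize = 1, nKernels = 1)
  p$W1 <- matrix(2, 1, 1); p$bias <- matrix(0, 1, 1)
  a <- 0.3; v <- 1.7
  x <- array(v, c(1, 1, 1))
  att <- list(alpha_w = a, alpha_k = matrix(a, 1, 1), alpha_c = a, alpha_o = a)
  got <- odconvForward(x, p, attention = att)
  expect_equal(as.vector(got), a^4 * 2 * v, tolerance = 1e-12)
})

test_that("computed attention matches a random-instance loop oracle", {
  set.seed(33)
  p <- odconvParams(3, 2, kernelSize = 3, nKernels = 2)
  x <- array(rnorm(3 * 6 * 6), c(3, 6, 6))
  att <- attentionBranch(x, p)
  got <- odconvForward(x, p)
  # assemble the effective kernel by hand from the attention arrays
  Weff <- matrix(0, 27, 2)
  rowscale <- as.vector(outer(as.vector(att$alpha_k), att$alpha_c)) # offset fast
  for (i in 1:2) {
    Wi <- p[[paste0("W", i)]] * att$alpha_w[i] * rowscale
    Wi <- sweep(Wi, 2, att$alpha_o, "*")
    Weff <- Weff + Wi
  }
  want <- sweep(conv_oracle(x, Weff, 3), 1, as.vector(p$bias), "+")
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("attention branch saturates and centres as sigmoid dictates", {
  p <- odconvParams(2, 2, kernelSize = 3, nKernels = 2)
  # zero input, zero weights, zero biases -> all attentions 0.5
  p$Ws[] <- 0; p$bs[] <- 0; p$Wh[] <- 0; p$bh[] <- 0
  att <- attentionBranch(array(0, c(2, 3, 3)), p)
  expect_true(all(unlist(att) == 0.5))
  # huge head biases -> attentions ~ 1
  p$bh[] <- 50
  att <- attentionBranch(array(rnorm(18), c(2, 3, 3)), p)
  expect_true(all(unlist(att) > 1 - 1e-10))
  # hand-computed straight line: one channel pathway
  p2 <- odconvParams(1, 1, kernelSize = 1, nKernels = 1)
  p2$Ws <- matrix(c(2, rep(0, ncol(p2$Ws) - 1)), 1)  # squeeze r>=8, use dim 1
  p2$bs[] <- 0
  p2$Wh[] <- 0; p2$Wh[1, ] <- 1; p2$bh[] <- 0
  x <- array(c(1, 2, 3, 4), c(1, 2, 2))              # GAP = 2.5
  att2 <- attentionBranch(x, p2)
  expect_equal(att2$alpha_w, 1 / (1 + exp(-relu_scalar(2.5 * 2))),
               tolerance = 1e-12)
})

test_that("attention values lie strictly inside (0, 1) for finite input", {
  set.seed(34)
  p <- odconvParams(2, 3, kernelSize = 3, nKernels = 4)
  for (i in 1:20) {
    att <- attentionBranch(array(rnorm(2 * 4 * 4, sd = 3), c(2, 4, 4)), p)
    v <- unlist(att)
    expect_true(all(v > 0 & v < 1))
  }
})

test_that("dynamic (kernel-only) mode is the degenerate case of omni", {
  set.seed(35)
  p <- odconvParams(2, 2, kernelSize = 3, nKernels = 3)
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  att <- attentionBranch(x, p)
  att1 <- att
  att1$alpha_k[] <- 1; att1$alpha_c[] <- 1; att1$alpha_o[] <- 1
  expect_equal(dynamicConvForward(x, p, attention = att),
               odconvForward(x, p, attention = att1), tolerance = 1e-10)
  # n = 1, alpha_w = 1: plain convolution
  p1 <- odconvParams(2, 2, kernelSize = 3, nKernels = 1)
  a1 <- ones_attention(p1)
  expect_equal(dynamicConvForward(x, p1, attention = a1),
               sweep(conv_oracle(x, p1$W1, 3), 1, as.vector(p1$bias), "+"),
               tolerance = 1e-10)
})

test_that("the layer with frozen attention is linear in the input", {
  set.seed(36)
  p <- odconvParams(2, 2, kernelSize = 3, nKernels = 2)
  att <- list(alpha_w = c(0.3, 0.8), alpha_k = matrix(runif(9), 3),
              alpha_c = runif(2), alpha_o = runif(2))
  p$bias[] <- 0
  x1 <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  x2 <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  f <- function(x) odconvForward(x, p, attention = att)
  expect_equal(f(2 * x1 + 3 * x2), 2 * f(x1) + 3 * f(x2), tolerance = 1e-9)
})
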