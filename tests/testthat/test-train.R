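# Full-network assembly, gradient correctness, training behaviour, LOOCV.

tiny_cfg <- function(epochs = 3L, seed = 1L, ...) {
  modelConfig(odconv = list(widths = c(4L, 8L), nKernels = 2L),
              capsule = list(capsDim = 4L, nOut = 2L, dOut = 4L, pool = 1L),
              vit = list(depth = 1L, heads = 2L, dModel = 16L, dPos = 4L),
              optim = list(lr = 1e-3, epochs = as.integer(epochs)),
              patchSize = 8, seed = seed, ...)
}

tiny_study <- function(nSections = 3L, seed = 7L) {
  cfg <- synthConfig(nSections = nSections, gridRows = 3, gridCols = 3,
                     spotSpacing = 16, nBlobs = 60, nGenes = 5, seed = seed)
  st <- makeSections(cfg)
  st$sections <- lapply(st$sections, function(s) {
    SummarizedExperiment::assays(s)$logcounts <-
      t(exprValues(normalizeCounts(sectionExpression(s, "counts"))))
    s
  })
  st
}

test_that("the assembled network produces finite predictions of right shape", {
  st <- tiny_study(1)
  m <- trainModel(st$sections, tiny_cfg(epochs = 1))
  pred <- predictSection(m, st$sections[[1]])
  expect_equal(dim(pred), c(9L, 5L))
  expect_true(all(is.finite(pred)))
})

test_that("ablating a module changes the predictions (non-degenerate wiring)", {
  st <- tiny_study(1)
  base <- predictSection(trainModel(st$sections, tiny_cfg(epochs = 1)),
                         st$sections[[1]])
  for (mod in c("odconv", "capsule", "vit", "gat")) {
    alt <- predictSection(trainModel(st$sections,
                                     tiny_cfg(epochs = 1, ablate = mod)),
                          st$sections[[1]])
    expect_false(isTRUE(all.equal(base, alt)), label = paste("ablate", mod))
    expect_true(all(is.finite(alt)))
  }
})

test_that("backpropagated gradients match finite differences through the net", {
  st <- tiny_study(1)
  cfg <- tiny_cfg()
  sec <- st$sections[[1]]
  prep <- histoexpr:::.prep_section(sec, cfg)
  model <- buildModel(cfg, 5L, 2, 2)
  params <- model@params
  lossAt <- function(pl) {
    tp <- histoexpr:::ag_tape()
    pget <- function(nm) histoexpr:::ag_const(tp, pl[[nm]])
    pred <- histoexpr:::.model_forward(tp, pget, model, prep$X, prep$spots,
                                       prep$graph)
    mean((histoexpr:::ag_val(pred) - prep$target)^2)
  }
  tp <- histoexpr:::ag_tape()
  pget <- function(nm) histoexpr:::ag_param(tp, params[[nm]], nm)
  pred <- histoexpr:::.model_forward(tp, pget, model, prep$X, prep$spots,
                                     prep$graph)
  loss <- histoexpr:::ag_mse(pred, prep$target)
  grads <- histoexpr:::ag_param_grads(tp, histoexpr:::ag_backward(tp, loss))
  # every parameter group receives gradient signal
  groups <- unique(sub("\\..*$", "", names(grads)))
  for (gp in groups) {
    tot <- sum(vapply(grads[grepl(paste0("^", gp, "\\."), names(grads))],
                      function(g) sum(abs(g)), numeric(1)))
    expect_gt(tot, 0)
  }
  # spot-check entries across representative groups by central differences
  eps <- 1e-5
  for (nm in c("od1.W1", "od2.Wh", "caps.Wroute", "caps.B", "pos.Ex",
               "fuse.Wf", "vit1.Wq", "vit1.Wf1", "gat.omega", "gat.a1",
               "head.W")) {
    set.seed(nchar(nm))
    i <- sample(length(params[[nm]]), 1)
    up <- params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
    fd <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("training loss decreases on a fixed section", {
  st <- tiny_study(1)
  m <- trainModel(st$sections, tiny_cfg(epochs = 25, seed = 2))
  h <- m@meta$lossHistory
  expect_lt(h[length(h)], h[1])
  sm <- stats::filter(h, rep(1 / 5, 5), sides = 1)[-(1:4)]  # rolling mean
  expect_lt(mean(diff(sm) > 0), 0.2)     # smoothed curve trends downward
})

test_that("same-seed training is bit-reproducible", {
  st <- tiny_study(2)
  a <- trainModel(st$sections, tiny_cfg(epochs = 2, seed = 5))
  b <- trainModel(st$sections, tiny_cfg(epochs = 2, seed = 5))
  expect_identical(a@params, b@params)
  expect_identical(predictSection(a, st$sections[[1]]),
                   predictSection(b, st$sections[[1]]))
  c2 <- trainModel(st$sections, tiny_cfg(epochs = 2, seed = 6))
  expect_false(identical(a@params, c2@params))
})

test_that("leave-one-out produces one model and PCC vector per section", {
  st <- tiny_study(3)
  ann <- lapply(st$groundTruth, makeAnnotation, k = 2)
  res <- trainLOOCV(st$sections, tiny_cfg(epochs = 2), annotations = ann)
  expect_length(res$models, 3L)
  expect_length(res$predictions, 3L)
  expect_equal(dim(genePcc(res$report)), c(5L, 3L))
  expect_true(all(is.finite(genePcc(res$report))))
  expect_length(meanPcc(res$report), 3L)
  expect_length(res$report@ari, 3L)
  expect_true(all(res$report@ari >= -1 & res$report@ari <= 1))
  expect_equal(nrow(res$report@geneRanking), 5L)
  expect_error(trainLOOCV(st$sections[1], tiny_cfg()), "at least two")
})
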