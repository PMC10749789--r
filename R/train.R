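# Training: full-batch gradient steps with Adam, one tissue section per
# optimisation step (the transformer and the graph attention operate on a
# whole section's spot set jointly), mean-squared error against the
# per-gene-standardised log-normalised expression.

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))), t = 0L)
}

.adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# prepare one section for the network: pixel matrix, spot table, graph,
# target, and the (constant) im2col of the pooled input for the first
# convolution layer, computed once and reused every step.
.prep_section <- function(section, cfg) {
  spots <- spotTable(section)
  patches <- extractPatches(slideImage(section), SpotTable(spots),
                            patchSize = cfg@patchSize)
  X <- .patch_matrix(patches)
  out <- list(X = X, spots = spots,
              graph = buildKnnGraph(SpotTable(spots), k = cfg@gat$k,
                                    coords = cfg@gat$coords),
              target = t(SummarizedExperiment::assay(section, "logcounts")))
  if (!"odconv" %in% cfg@ablate) {
    P <- nrow(spots)
    S <- as.integer(cfg@patchSize)
    ip <- cfg@odconv$inputPool
    Xp <- X
    h <- S
    if (ip > 1L) {
      Xp <- rowsum(X, .pool_groups(S, S, ip, P)) / ip^2
      h <- S %/% ip
    }
    out$xc1 <- im2col_apply(Xp, im2col_index(h, h, cfg@odconv$kernelSize, P))
  }
  out
}

#' Train the full model on a set of sections
#'
#' One Adam step per section per epoch, in fixed section order; the loss is
#' the mean squared error between the predicted and the per-gene standardised
#' log-normalised expression (standardisation moments are estimated on the
#' training sections and inverted at prediction time). Deterministic given
#' the configuration seed.
#'
#' @param sections list of \linkS4class{STSection} carrying a
#'   \code{logcounts} assay and a slide image.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param verbose print the per-epoch mean loss.
#' @return a fitted \linkS4class{HistoModel}; the per-epoch training loss is
#'   in \code{meta$lossHistory}.
#' @export
trainModel <- function(sections, cfg = deskModelConfig(), verbose = FALSE) {
  stopifnot(length(sections) >= 1L)
  prep <- lapply(sections, .prep_section, cfg = cfg)
  genes <- rownames(sections[[1]])
  alltgt <- do.call(rbind, lapply(prep, `[[`, "target"))
  mu <- colMeans(alltgt)
  sg <- pmax(apply(alltgt, 2L, stats::sd), 1e-8)
  for (i in seq_along(prep))
    prep[[i]]$target <- sweep(sweep(prep[[i]]$target, 2L, mu), 2L, sg, "/")
  maxx <- max(vapply(prep, function(p) max(p$spots$array_x), numeric(1)))
  maxy <- max(vapply(prep, function(p) max(p$spots$array_y), numeric(1)))
  model <- buildModel(cfg, length(genes), maxx, maxy)
  params <- model@params
  st <- .adam_init(params)
  cache <- new.env(parent = emptyenv())
  hist <- numeric(cfg@optim$epochs)
  for (ep in seq_len(cfg@optim$epochs)) {
    tot <- 0
    for (p in prep) {
      tp <- ag_tape()
      nodes <- new.env(parent = emptyenv())
      pget <- function(nm) {
        if (!exists(nm, envir = nodes, inherits = FALSE))
          assign(nm, ag_param(tp, params[[nm]], nm), envir = nodes)
        get(nm, envir = nodes, inherits = FALSE)
      }
      pred <- .model_forward(tp, pget, model, p$X, p$spots, p$graph,
                             cache = cache, xc1 = p$xc1)
      loss <- ag_mse(pred, p$target)
      tot <- tot + ag_val(loss)[1]
      grads <- ag_param_grads(tp, ag_backward(tp, loss))
      upd <- .adam_step(params, grads, st, cfg@optim$lr)
      params <- upd$params; st <- upd$state
    }
    hist[ep] <- tot / length(prep)
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, hist[ep]))
  }
  model@params <- params
  model@meta$genes <- genes
  model@meta$targetMu <- mu
  model@meta$targetSd <- sg
  model@meta$lossHistory <- hist
  model
}

#' Predict expression for a section
#'
#' Runs the fitted network on the section's image patches and spot layout and
#' returns predictions on the log-normalised expression scale (the training
#' standardisation is inverted).
#'
#' @param model a fitted \linkS4class{HistoModel}.
#' @param section an \linkS4class{STSection} with a slide image.
#' @return spots x genes numeric matrix.
#' @export
predictSection <- function(model, section) {
  cfg <- model@config
  p <- .prep_section(section, cfg)
  tp <- ag_tape()
  pget <- function(nm) ag_const(tp, model@params[[nm]])
  pred <- ag_val(.model_forward(tp, pget, model, p$X, p$spots, p$graph,
                                xc1 = p$xc1))
  pred <- sweep(sweep(pred, 2L, model@meta$targetSd, "*"), 2L, model@meta$targetMu, "+")
  dimnames(pred) <- list(p$spots$spot_id, model@meta$genes)
  pred
}

#' Leave-one-out cross-validation over sections
#'
#' For each section, trains on all the others and predicts the held-out
#' section, recording the per-gene Pearson correlation and its p-value on the
#' held-out spots. Optionally evaluates spatial-domain recovery by K-means
#' clustering of the predicted expression against supplied annotations.
#'
#' @param sections list of >= 2 \linkS4class{STSection} with \code{logcounts}
#'   and images.
#' @param cfg a \linkS4class{ModelConfig}; fold f uses seed
#'   \code{cfg@seed + f} for its parameter initialisation.
#' @param annotations optional list (parallel to \code{sections}) of integer
#'   partitions for \code{\link{clusterEval}}; NULL entries are skipped.
#' @param verbose print progress.
#' @return list with \code{report} (an \linkS4class{EvalReport}),
#'   \code{predictions} (per-section matrices) and \code{models}.
#' @export
trainLOOCV <- function(sections, cfg = deskModelConfig(), annotations = NULL,
                       verbose = FALSE) {
  if (length(sections) < 2L) stop("leave-one-out needs at least two sections")
  genes <- rownames(sections[[1]])
  secIds <- vapply(sections, sectionId, character(1))
  nsec <- length(sections)
  pccs <- pvals <- matrix(NA_real_, length(genes), nsec,
                          dimnames = list(genes, secIds))
  preds <- vector("list", nsec); models <- vector("list", nsec)
  aris <- numeric(0)
  for (f in seq_len(nsec)) {
    if (verbose) message("fold ", f, "/", nsec, ": holding out ", secIds[f])
    foldCfg <- cfg
    foldCfg@seed <- cfg@seed + f
    model <- trainModel(sections[-f], foldCfg, verbose = FALSE)
    pred <- predictSection(model, sections[[f]])
    truth <- t(SummarizedExperiment::assay(sections[[f]], "logcounts"))
    n <- nrow(truth)
    for (g in seq_along(genes)) {
      r <- pcc(truth[, g], pred[, g])
      pccs[g, f] <- r
      pvals[g, f] <- pccPvalue(r, n)
    }
    preds[[f]] <- pred
    models[[f]] <- model
    if (!is.null(annotations) && !is.null(annotations[[f]])) {
      k <- length(unique(annotations[[f]]))
      aris[secIds[f]] <- clusterEval(pred, annotations[[f]], k,
                                     seed = cfg@seed)
    }
  }
  mp <- apply(pccs, 2L, function(x) mean(x[is.finite(x)]))
  report <- new("EvalReport", pcc = pccs, pvalues = pvals, meanPcc = mp,
                ari = aris,
                geneRanking = data.frame(),
                provenance = list(configHash = configHash(cfg),
                                  seed = cfg@seed,
                                  nSections = nsec, nGenes = length(genes)))
  report@geneRanking <- rankGenes(report)
  list(report = report, predictions = preds, models = models)
}
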