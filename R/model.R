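#' Model configuration
#'
#' Collects every architecture hyperparameter left open by the method
#' description. Defaults are the package's declared reference configuration;
#' \code{\link{deskModelConfig}} gives a small CPU-friendly variant used for
#' the synthetic desk benchmark.
#'
#' @slot odconv list: \code{layers}, \code{widths} (output channels per
#'   layer), \code{kernelSize}, \code{nKernels}, \code{kernelAttention}
#'   ("sigmoid" or "softmax" for the kernel-mixture head), \code{pool}
#'   (average-pool factor after each layer).
#' @slot capsule list: \code{kernelSize}, \code{capsDim} (primary capsule
#'   dimension d), \code{nOut}, \code{dOut} (output capsule count and
#'   dimension), \code{pool}.
#' @slot vit list: \code{depth}, \code{heads}, \code{dModel}, \code{dPos}
#'   (per-axis position embedding width).
#' @slot gat list: \code{slope} (LeakyReLU negative slope), \code{coords}
#'   ("pixel" or "array" for the k-NN graph), \code{k} (neighbours),
#'   \code{mOut}.
#' @slot optim list: \code{lr}, \code{epochs}.
#' @slot patchSize patch side length in pixels.
#' @slot ablate character subset of c("odconv", "capsule", "vit", "gat"):
#'   modules to replace by a pass-through for ablation runs.
#' @slot seed integer seed for parameter initialisation and training order.
#' @export
setClass("ModelConfig",
         representation(odconv = "list", capsule = "list", vit = "list",
                        gat = "list", optim = "list", patchSize = "numeric",
                        ablate = "character", seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (object@vit$dModel %% object@vit$heads != 0)
    return("dModel must be divisible by the head count")
  if (object@odconv$kernelSize %% 2 != 1) return("kernel size must be odd")
  if (!all(object@ablate %in% c("odconv", "capsule", "vit", "gat")))
    return("unknown ablation target")
  TRUE
})

#' @rdname ModelConfig-class
#' @param odconv,capsule,vit,gat,optim,patchSize,ablate,seed see slots.
#' @export
modelConfig <- function(odconv = list(), capsule = list(), vit = list(),
                        gat = list(), optim = list(), patchSize = 112,
                        ablate = character(0), seed = 1L) {
  od <- utils::modifyList(list(layers = 2L, widths = c(32L, 64L),
                               kernelSize = 3L, nKernels = 4L,
                               kernelAttention = "sigmoid", pool = c(2L, 2L),
                               inputPool = 1L),
                          odconv)
  cp <- utils::modifyList(list(kernelSize = 3L, capsDim = 8L, nOut = 16L,
                               dOut = 16L, pool = 2L), capsule)
  vt <- utils::modifyList(list(depth = 4L, heads = 8L, dModel = 512L,
                               dPos = 16L), vit)
  gt <- utils::modifyList(list(slope = 0.2, coords = "pixel", k = 4L,
                               mOut = NULL), gat)
  if (is.null(gt$mOut)) gt$mOut <- vt$dModel
  op <- utils::modifyList(list(lr = 1e-4, epochs = 100L), optim)
  new("ModelConfig", odconv = od, capsule = cp, vit = vt, gat = gt,
      optim = op, patchSize = patchSize, ablate = ablate,
      seed = as.integer(seed))
}

#' Desk-scale configuration for the synthetic benchmark
#'
#' A narrow variant sized for CPU training on the default synthetic study
#' (4 sections of 8 x 8 spots): 32-pixel patches, conv widths 16/32,
#' capsule 8 x 16, 2 transformer blocks of 4 heads at width 64.
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param ... further overrides passed to \code{\link{modelConfig}}.
#' @return a \linkS4class{ModelConfig}.
#' @export
deskModelConfig <- function(epochs = 40L, lr = 1e-3, seed = 1L, ...) {
  modelConfig(odconv = list(widths = c(16L, 32L), inputPool = 2L),
              capsule = list(nOut = 8L, dOut = 16L, pool = 1L),
              vit = list(depth = 2L, heads = 4L, dModel = 64L),
              optim = list(lr = lr, epochs = as.integer(epochs)),
              patchSize = 32, seed = seed, ...)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig [%s]: patch %d | odconv %s (k=%d, n=%d) | ",
                     "caps d=%d -> %dx%d | vit %dx%dh d=%d | gat k=%d | ",
                     "lr=%g epochs=%d | seed %d%s\n"),
              configHash(object), object@patchSize,
              paste(object@odconv$widths, collapse = "-"),
              object@odconv$kernelSize, object@odconv$nKernels,
              object@capsule$capsDim, object@capsule$nOut, object@capsule$dOut,
              object@vit$depth, object@vit$heads, object@vit$dModel,
              object@gat$k, object@optim$lr, object@optim$epochs, object@seed,
              if (length(object@ablate))
                paste0(" | ablate: ", paste(object@ablate, collapse = ","))
              else ""))
})

#' Stable short hash of a configuration (for provenance logs)
#' @param x any R object.
#' @return 8-hex-digit string.
#' @export
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

## ---- model construction -----------------------------------------------------

#' Fitted (or freshly initialised) prediction model
#'
#' @slot config the \linkS4class{ModelConfig}.
#' @slot params named list of numeric parameter arrays.
#' @slot meta list: gene names, dimension trace, target standardisation,
#'   training loss history.
#' @export
setClass("HistoModel",
         representation(config = "ModelConfig", params = "list", meta = "list"))

setMethod("show", "HistoModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("HistoModel: %d parameters in %d arrays; genes: %d\n",
              np, length(object@params), length(object@meta$genes)))
  show(object@config)
})

# dimension trace through the network for a given config
.model_dims <- function(cfg) {
  S <- as.integer(cfg@patchSize)
  od <- cfg@odconv; cp <- cfg@capsule; vt <- cfg@vit
  sdim <- S %/% od$inputPool
  if (!"odconv" %in% cfg@ablate) {
    for (l in seq_len(od$layers)) sdim <- sdim %/% od$pool[l]
    C <- od$widths[od$layers]
  } else {
    # pass-through: pool the raw RGB patch onto the conv output grid
    for (l in seq_len(od$layers)) sdim <- sdim %/% od$pool[l]
    C <- 3L
  }
  capsSpatial <- sdim %/% cp$pool
  # capsules are cut from the incoming channels; when the conv stack is
  # ablated the raw RGB channels form one capsule group of dimension 3
  capsDim <- if ("odconv" %in% cfg@ablate) C else cp$capsDim
  ncaps <- capsSpatial^2 * (C %/% capsDim)
  capsFeat <- if ("capsule" %in% cfg@ablate) C else cp$nOut * cp$dOut
  if (!"capsule" %in% cfg@ablate && C %% capsDim != 0)
    stop("capsDim must divide the final conv width")
  list(S = S, C = C, sdim = sdim, capsSpatial = capsSpatial, ncaps = ncaps,
       capsDim = capsDim, capsFeat = capsFeat,
       fuseIn = capsFeat + 2L * vt$dPos,
       dModel = vt$dModel, M = vt$dModel, mOut = cfg@gat$mOut)
}

#' Assemble a model
#'
#' Initialises every parameter group of the full pipeline: the dynamic
#' convolution stack, the capsule stage, position embeddings and fusion, the
#' transformer encoder, the graph attention layer and the expression head.
#' Modules listed in \code{config@ablate} are replaced by pass-throughs at
#' forward time and their parameters are omitted.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param nGenes size of the gene panel.
#' @param maxArrayX,maxArrayY largest array coordinates across the training
#'   sections (sizes the position-embedding tables).
#' @return a \linkS4class{HistoModel} with freshly initialised parameters.
#' @export
buildModel <- function(cfg, nGenes, maxArrayX, maxArrayY) {
  set.seed(cfg@seed)
  dm <- .model_dims(cfg)
  od <- cfg@odconv; cp <- cfg@capsule; vt <- cfg@vit
  params <- list()
  add <- function(lst, prefix) {
    for (nm in names(lst)) if (nm != "dims")
      params[[paste0(prefix, ".", nm)]] <<- lst[[nm]]
  }
  if (!"odconv" %in% cfg@ablate) {
    cin <- 3L
    for (l in seq_len(od$layers)) {
      add(.od_init(cin, od$widths[l], od$kernelSize, od$nKernels),
          paste0("od", l))
      cin <- od$widths[l]
    }
  }
  if (!"capsule" %in% cfg@ablate) {
    add(capsuleConvParams(dm$C, cp$kernelSize), "caps")
    params[["caps.Wroute"]] <- array(
      stats::rnorm(dm$ncaps * dm$capsDim * cp$nOut * cp$dOut,
                   sd = sqrt(1 / dm$capsDim)),
      c(dm$ncaps, dm$capsDim, cp$nOut * cp$dOut))
    params[["caps.B"]] <- matrix(0, dm$ncaps, cp$nOut)
  }
  pe <- positionEmbedding(maxArrayX, maxArrayY, vt$dPos)
  params[["pos.Ex"]] <- pe$Ex
  params[["pos.Ey"]] <- pe$Ey
  params[["fuse.Wf"]] <- matrix(stats::rnorm(dm$fuseIn * vt$dModel,
                                             sd = sqrt(1 / dm$fuseIn)),
                                dm$fuseIn, vt$dModel)
  params[["fuse.bf"]] <- matrix(0, 1, vt$dModel)
  if (!"vit" %in% cfg@ablate)
    for (l in seq_len(vt$depth)) add(.vit_block_params(vt$dModel), paste0("vit", l))
  if (!"gat" %in% cfg@ablate) {
    add(gatParams(dm$M, cfg@gat$mOut), "gat")
    headIn <- cfg@gat$mOut
  } else headIn <- dm$M
  params[["head.W"]] <- matrix(stats::rnorm(headIn * nGenes,
                                            sd = sqrt(1 / headIn)),
                               headIn, nGenes)
  params[["head.b"]] <- matrix(0, 1, nGenes)
  new("HistoModel", config = cfg, params = params,
      meta = list(dims = dm, nGenes = nGenes,
                  maxArrayX = maxArrayX, maxArrayY = maxArrayY,
                  configHash = configHash(cfg)))
}

# full network forward on a tape.
# X: ((P*S*S) x 3) constant matrix of patch pixels; spotdf: spot data.frame;
# graph: SpotGraph. pget maps parameter names to nodes. cache memoises index
# structures across steps; xc1 is the (constant) im2col of the pooled input,
# precomputable once per section. Returns (P x G) node.
.model_forward <- function(tape, pget, model, X, spotdf, graph,
                           cache = NULL, xc1 = NULL) {
  cfg <- model@config
  dm <- model@meta$dims
  od <- cfg@odconv; cp <- cfg@capsule; vt <- cfg@vit
  P <- nrow(spotdf)
  x <- ag_const(tape, X)
  h <- w <- dm$S
  if (od$inputPool > 1L) {
    grp <- .pool_groups(h, w, od$inputPool, P)
    h <- w <- h %/% od$inputPool
    x <- ag_rowsum_groups(x, grp, P * h * w, average = TRUE)
  }
  if (!"odconv" %in% cfg@ablate) {
    cin <- 3L
    for (l in seq_len(od$layers)) {
      dims <- list(cIn = cin, cOut = od$widths[l], k = od$kernelSize,
                   n = od$nKernels)
      x <- ag_relu(.od_layer(tape, x, pget, paste0("od", l), dims, h, w, P,
                             od$kernelAttention, cache = cache,
                             xcPre = if (l == 1L) xc1 else NULL))
      if (od$pool[l] > 1L) {
        grp <- .pool_groups(h, w, od$pool[l], P)
        h <- h %/% od$pool[l]; w <- w %/% od$pool[l]
        x <- ag_rowsum_groups(x, grp, P * h * w, average = TRUE)
      }
      cin <- od$widths[l]
    }
  } else {
    total <- h %/% dm$sdim
    if (total > 1L) {
      grp <- .pool_groups(h, w, total, P)
      h <- w <- dm$sdim
      x <- ag_rowsum_groups(x, grp, P * h * w, average = TRUE)
    }
  }
  if (!"capsule" %in% cfg@ablate) {
    caps <- .caps_primary(tape, x, pget, "caps", h, w, P, dm$C, dm$capsDim,
                          k = cp$kernelSize, pool = cp$pool, cache = cache)
    feat <- .caps_route(tape, caps, pget, "caps", P, dm$ncaps, dm$capsDim,
                        cp$nOut, cp$dOut)
  } else {
    feat <- ag_rowsum_groups(x, rep(seq_len(P), each = h * w), P,
                             average = TRUE)
  }
  ex <- ag_rows(pget("pos.Ex"), spotdf$array_x + 1L)
  ey <- ag_rows(pget("pos.Ey"), spotdf$array_y + 1L)
  tok <- ag_addbias(ag_matmul(ag_cbind(feat, ex, ey), pget("fuse.Wf")),
                    pget("fuse.bf"))
  if (!"vit" %in% cfg@ablate)
    for (l in seq_len(vt$depth))
      tok <- .vit_block(tape, tok, pget, paste0("vit", l), vt$heads)
  hgat <- if (!"gat" %in% cfg@ablate)
    .gat_fwd(tape, tok, pget, "gat", graph, cfg@gat$slope)
  else tok
  ag_addbias(ag_matmul(hgat, pget("head.W")), pget("head.b"))
}

# convert a PatchStack to the ((P*S*S) x 3) pixel-major matrix the forward
# pass consumes (pixel index column-major within each patch)
.patch_matrix <- function(patches) {
  a <- patchArray(patches)
  d <- dim(a)                                   # P x 3 x S x S
  m <- aperm(a, c(3, 4, 1, 2))                  # S x S x P x 3
  dim(m) <- c(d[3] * d[4] * d[1], 3L)
  m
}
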