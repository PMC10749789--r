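#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

## ---- ExpressionMatrix ------------------------------------------------------

#' Spot-by-gene expression values
#'
#' A thin validated container for a spots x genes matrix together with its
#' processing state: \code{"raw_counts"} (non-negative integers straight from
#' the count file) or \code{"normalized"} (counts-per-million scaled and
#' natural-log transformed, see \code{\link{normalizeCounts}}).
#'
#' @slot values numeric matrix, spots as rows, genes as columns; column names
#'   are the gene names, row names the spot identifiers.
#' @slot state either \code{"raw_counts"} or \code{"normalized"}.
#' @export
setClass("ExpressionMatrix",
         representation(values = "matrix", state = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!object@state %in% c("raw_counts", "normalized"))
    return("state must be 'raw_counts' or 'normalized'")
  if (is.null(colnames(v))) return("values must carry gene names as colnames")
  if (anyNA(v)) return("values contain NA")
  if (any(v < 0)) return("expression values must be non-negative")
  if (object@state == "raw_counts" && any(v != round(v)))
    return("raw counts must be integers")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values spots x genes numeric matrix with gene names as colnames.
#' @param state \code{"raw_counts"} or \code{"normalized"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, state = c("raw_counts", "normalized")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  new("ExpressionMatrix", values = values, state = state)
}

#' @rdname ExpressionMatrix
#' @param object,x an \code{ExpressionMatrix}.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname ExpressionMatrix
#' @export
setGeneric("exprState", function(x) standardGeneric("exprState"))

#' @rdname ExpressionMatrix
#' @export
setMethod("exprState", "ExpressionMatrix", function(x) x@state)

#' @rdname ExpressionMatrix
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname ExpressionMatrix
#' @export
setMethod("geneNames", "ExpressionMatrix", function(x) colnames(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d spots x %d genes [%s]\n",
              nrow(object@values), ncol(object@values), object@state))
})

#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

## ---- SpotTable -------------------------------------------------------------

#' Spot metadata table
#'
#' Holds spot identities, integer array coordinates on the capture grid and
#' pixel coordinates on the slide image. Array coordinates drive the learned
#' position embeddings; pixel coordinates drive patch extraction and the
#' 4-nearest-neighbour spot graph.
#'
#' @slot spots data.frame with columns \code{spot_id}, \code{section_id},
#'   \code{array_x}, \code{array_y} (non-negative integers), \code{pixel_x},
#'   \code{pixel_y} (numeric, image columns / rows).
#' @export
setClass("SpotTable", representation(spots = "data.frame"))

setValidity("SpotTable", function(object) {
  df <- object@spots
  need <- c("spot_id", "section_id", "array_x", "array_y", "pixel_x", "pixel_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(paste(df$section_id, df$spot_id)))
    return("spot_id must be unique within a section")
  if (any(df$array_x < 0) || any(df$array_y < 0))
    return("array coordinates must be non-negative")
  if (any(df$array_x != round(df$array_x)) || any(df$array_y != round(df$array_y)))
    return("array coordinates must be integers")
  if (!is.numeric(df$pixel_x) || !is.numeric(df$pixel_y))
    return("pixel coordinates must be numeric")
  TRUE
})

#' Construct a SpotTable
#' @param spots data.frame, see \linkS4class{SpotTable}.
#' @return A \linkS4class{SpotTable}.
#' @export
SpotTable <- function(spots) new("SpotTable", spots = as.data.frame(spots))

#' @rdname SpotTable
#' @param x a \code{SpotTable} (or object carrying one).
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))

#' @rdname SpotTable
#' @export
setMethod("spotTable", "SpotTable", function(x) x@spots)

#' @export
setMethod("length", "SpotTable", function(x) nrow(x@spots))

setMethod("show", "SpotTable", function(object) {
  cat(sprintf("SpotTable: %d spots, section(s): %s\n", nrow(object@spots),
              paste(unique(object@spots$section_id), collapse = ", ")))
})

## ---- PatchStack ------------------------------------------------------------

#' Per-spot RGB image patches
#'
#' @slot patches numeric array N x 3 x H x W in [0, 1], one patch per spot,
#'   aligned with the SpotTable rows it was built from.
#' @slot spotIds character vector of length N.
#' @export
setClass("PatchStack",
         representation(patches = "array", spotIds = "character"))

setValidity("PatchStack", function(object) {
  d <- dim(object@patches)
  if (length(d) != 4L || d[2] != 3L) return("patches must be N x 3 x H x W")
  if (d[1] != length(object@spotIds)) return("spotIds length must equal N")
  if (length(object@patches) &&
      (min(object@patches) < 0 || max(object@patches) > 1))
    return("patch values must lie in [0, 1]")
  TRUE
})

setMethod("show", "PatchStack", function(object) {
  d <- dim(object@patches)
  cat(sprintf("PatchStack: %d patches of 3 x %d x %d\n", d[1], d[3], d[4]))
})

#' @rdname PatchStack-class
#' @param x a \code{PatchStack}.
#' @export
setGeneric("patchArray", function(x) standardGeneric("patchArray"))

#' @rdname PatchStack-class
#' @export
setMethod("patchArray", "PatchStack", function(x) x@patches)

## ---- STSection -------------------------------------------------------------

#' One tissue section: counts, spots and slide image
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: genes are rows,
#' spots are columns, the spot table lives in \code{colData} and the RGB slide
#' image (H x W x 3, values in [0, 1]) in the \code{image} slot. The section
#' is the unit of model training and of leave-one-out cross-validation.
#'
#' @slot image numeric array H x W x 3 in [0, 1] (may be empty).
#' @slot sectionId scalar character.
#' @export
setClass("STSection", contains = "SummarizedExperiment",
         representation(image = "array", sectionId = "character"))

setValidity("STSection", function(object) {
  if (length(object@sectionId) != 1L) return("sectionId must be scalar")
  if (length(object@image)) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
    if (min(object@image) < 0 || max(object@image) > 1)
      return("image values must lie in [0, 1]")
  }
  need <- c("array_x", "array_y", "pixel_x", "pixel_y")
  if (!all(need %in% names(colData(object))))
    return("colData must contain array_x, array_y, pixel_x, pixel_y")
  TRUE
})

#' Construct an STSection
#'
#' @param spots a \linkS4class{SpotTable} (single section).
#' @param expr an \linkS4class{ExpressionMatrix} whose rows match the spot
#'   table rows (matched by spot id when both are named).
#' @param image optional H x W x 3 RGB array in [0, 1].
#' @return An \linkS4class{STSection}.
#' @export
STSection <- function(spots, expr, image = NULL) {
  df <- spotTable(spots)
  v <- exprValues(expr)
  if (!is.null(rownames(v)) && all(df$spot_id %in% rownames(v)))
    v <- v[df$spot_id, , drop = FALSE]
  if (nrow(v) != nrow(df))
    stop("expression matrix rows do not match spot table rows")
  assayname <- if (exprState(expr) == "raw_counts") "counts" else "logcounts"
  assaylist <- stats::setNames(list(t(v)), assayname)
  se <- SummarizedExperiment(assays = assaylist,
                             colData = DataFrame(df, row.names = df$spot_id))
  new("STSection", se, image = if (is.null(image)) array(0, c(0, 0, 0)) else image,
      sectionId = as.character(df$section_id[1]))
}

#' @rdname STSection
#' @param x an \code{STSection}.
#' @export
setGeneric("sectionId", function(x) standardGeneric("sectionId"))

#' @rdname STSection
#' @export
setMethod("sectionId", "STSection", function(x) x@sectionId)

#' @rdname STSection
#' @export
setGeneric("slideImage", function(x) standardGeneric("slideImage"))

#' @rdname STSection
#' @export
setMethod("slideImage", "STSection", function(x) x@image)

#' @rdname STSection
#' @export
setMethod("spotTable", "STSection", function(x) {
  as.data.frame(colData(x))
})

#' Expression of a section as an ExpressionMatrix
#' @rdname STSection
#' @param assayName which assay to extract ("counts" or "logcounts").
#' @export
sectionExpression <- function(x, assayName = NULL) {
  if (is.null(assayName))
    assayName <- if ("logcounts" %in% names(assays(x))) "logcounts" else "counts"
  state <- if (assayName == "counts") "raw_counts" else "normalized"
  ExpressionMatrix(t(assay(x, assayName)), state = state)
}

setMethod("show", "STSection", function(object) {
  cat(sprintf("STSection '%s': %d genes x %d spots; image: %s; assays: %s\n",
              object@sectionId, nrow(object), ncol(object),
              if (length(object@image)) paste(dim(object@image)[1:2], collapse = "x")
              else "none",
              paste(names(assays(object)), collapse = ", ")))
})

## ---- SpotGraph -------------------------------------------------------------

#' Directed k-nearest-neighbour spot graph
#'
#' Edges i -> j mean "j is one of the k nearest neighbours of i" under
#' Euclidean distance on pixel coordinates; each node has out-degree
#' min(k, N - 1) and no self-loops.
#'
#' @slot nNodes number of spots.
#' @slot edges integer matrix with columns \code{from}, \code{to}, ordered by
#'   \code{from} then neighbour rank.
#' @slot distances Euclidean edge lengths, parallel to \code{edges}.
#' @slot k neighbour count requested.
#' @export
setClass("SpotGraph",
         representation(nNodes = "integer", edges = "matrix",
                        distances = "numeric", k = "integer"))

setValidity("SpotGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns (from, to)")
  if (nrow(e) != length(object@distances))
    return("distances must parallel edges")
  if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
  if (any(e < 1 | e > object@nNodes)) return("edge endpoint out of range")
  if (any(object@distances < 0)) return("distances must be non-negative")
  TRUE
})

setMethod("show", "SpotGraph", function(object) {
  cat(sprintf("SpotGraph: %d nodes, %d directed edges (k = %d)\n",
              object@nNodes, nrow(object@edges), object@k))
})

#' @rdname SpotGraph-class
#' @param x a \code{SpotGraph}.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname SpotGraph-class
#' @export
setMethod("graphEdges", "SpotGraph", function(x) {
  data.frame(from = x@edges[, 1], to = x@edges[, 2], distance = x@distances)
})

## ---- EvalReport ------------------------------------------------------------

#' Evaluation report of a cross-validated run
#'
#' @slot pcc genes x sections matrix of per-gene Pearson correlations on
#'   held-out spots (NaN where a gene had zero variance).
#' @slot pvalues genes x sections matrix of two-sided correlation p-values.
#' @slot meanPcc named per-section mean over genes of finite per-gene PCCs.
#' @slot ari named numeric, adjusted Rand index per annotated section
#'   (may be empty).
#' @slot geneRanking data.frame of genes sorted by mean -log10 p, descending.
#' @slot provenance list: config hash, seed, data fingerprint.
#' @export
setClass("EvalReport",
         representation(pcc = "matrix", pvalues = "matrix", meanPcc = "numeric",
                        ari = "numeric", geneRanking = "data.frame",
                        provenance = "list"))

setValidity("EvalReport", function(object) {
  ok <- is.finite(object@pcc)
  if (any(object@pcc[ok] < -1 - 1e-9 | object@pcc[ok] > 1 + 1e-9))
    return("PCC outside [-1, 1]")
  if (length(object@ari) && any(object@ari < -1 | object@ari > 1 + 1e-9))
    return("ARI outside [-1, 1]")
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d genes x %d sections\n",
              nrow(object@pcc), ncol(object@pcc)))
  cat("  mean held-out PCC per section:\n")
  print(round(object@meanPcc, 4))
  if (length(object@ari)) {
    cat("  ARI per annotated section:\n")
    print(round(object@ari, 4))
  }
})

#' @rdname EvalReport-class
#' @param x an \code{EvalReport}.
#' @export
setGeneric("meanPcc", function(x) standardGeneric("meanPcc"))

#' @rdname EvalReport-class
#' @export
setMethod("meanPcc", "EvalReport", function(x) x@meanPcc)

#' @rdname EvalReport-class
#' @export
setGeneric("genePcc", function(x) standardGeneric("genePcc"))

#' @rdname EvalReport-class
#' @export
setMethod("genePcc", "EvalReport", function(x) x@pcc)
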