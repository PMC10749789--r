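#' Preprocessing configuration
#'
#' Thresholds of the standard filtering pipeline for spatial transcriptomics
#' sections: sections must have strictly more than \code{minSpotsPerSection}
#' spots; genes must be expressed (count > 0) in at least
#' \code{minSpotsPerGene} spots pooled over all sections; the
#' \code{nHvg} most variable genes (variance of the log-normalized values)
#' are kept; normalization scales each spot's counts to \code{scaleFactor}
#' total before the ln(1 + x) transform.
#'
#' @slot minSpotsPerSection integer, default 180.
#' @slot minSpotsPerGene integer, default 1000.
#' @slot nHvg integer, default 1000.
#' @slot scaleFactor numeric, default 1e6 (counts-per-million style scaling).
#' @export
setClass("PreprocessConfig",
         representation(minSpotsPerSection = "numeric",
                        minSpotsPerGene = "numeric",
                        nHvg = "numeric", scaleFactor = "numeric"))

setValidity("PreprocessConfig", function(object) {
  v <- c(object@minSpotsPerSection, object@minSpotsPerGene,
         object@nHvg, object@scaleFactor)
  if (any(v <= 0)) return("all thresholds must be strictly positive")
  TRUE
})

#' @rdname PreprocessConfig-class
#' @param minSpotsPerSection,minSpotsPerGene,nHvg,scaleFactor see slots.
#' @export
preprocessConfig <- function(minSpotsPerSection = 180, minSpotsPerGene = 1000,
                             nHvg = 1000, scaleFactor = 1e6) {
  new("PreprocessConfig", minSpotsPerSection = minSpotsPerSection,
      minSpotsPerGene = minSpotsPerGene, nHvg = nHvg, scaleFactor = scaleFactor)
}

#' Retain sections with enough spots
#'
#' @param sections list of \linkS4class{STSection}.
#' @param minSpots sections with spot count strictly greater than this are
#'   retained (default 180).
#' @return The filtered list (a warning, not an error, when empty).
#' @export
filterSections <- function(sections, minSpots = 180) {
  keep <- vapply(sections, ncol, integer(1)) > minSpots
  if (!any(keep)) warning("no section passes the spot-count filter")
  sections[keep]
}

.expr_list <- function(sections, assayName = NULL) {
  lapply(sections, function(s) {
    if (is(s, "STSection")) exprValues(sectionExpression(s, assayName))
    else exprValues(s)
  })
}

#' Genes expressed in enough spots
#'
#' A gene is "expressed" in a spot when its raw count is > 0; counts of
#' expressing spots are pooled across all sections.
#'
#' @param sections list of \linkS4class{STSection} or
#'   \linkS4class{ExpressionMatrix} (raw counts), sharing one gene namespace.
#' @param minSpots keep genes expressed in at least this many spots.
#' @return Character vector of retained gene names, in input order.
#' @export
filterGenes <- function(sections, minSpots = 1000) {
  vals <- .expr_list(sections, "counts")
  genes <- colnames(vals[[1]])
  for (v in vals)
    if (!identical(colnames(v), genes))
      stop("sections do not share one gene namespace")
  nexpr <- Reduce(`+`, lapply(vals, function(v) colSums(v > 0)))
  genes[nexpr >= minSpots]
}

#' Top highly variable genes
#'
#' Ranks genes by the variance of their normalized (log) values pooled across
#' sections and keeps the top \code{n}; ties at the cutoff are broken by
#' gene-name order.
#'
#' @param sections list of normalized \linkS4class{ExpressionMatrix} or
#'   \linkS4class{STSection} with a \code{logcounts} assay.
#' @param n number of genes to keep.
#' @return Character vector of the selected gene names (input order).
#' @export
selectHVG <- function(sections, n = 1000) {
  vals <- .expr_list(sections, "logcounts")
  pooled <- do.call(rbind, vals)
  genes <- colnames(pooled)
  if (n >= length(genes)) {
    if (n > length(genes)) warning("n exceeds gene count; keeping all genes")
    return(genes)
  }
  v <- apply(pooled, 2L, stats::var)
  ord <- order(-v, genes)               # variance desc, then name asc
  genes[sort(ord[seq_len(n)])]
}

#' Normalize raw counts
#'
#' Per spot: \eqn{v_{ij} = \ln(1 + scale \cdot c_{ij} / \sum_j c_{ij})}. Spots
#' with zero total counts map to all-zero rows.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with state
#'   \code{"raw_counts"}.
#' @param scale library-size scale factor (default 1e6).
#' @return A normalized \linkS4class{ExpressionMatrix}.
#' @export
normalizeCounts <- function(expr, scale = 1e6) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (exprState(expr) != "raw_counts")
    stop("normalizeCounts expects raw counts")
  v <- exprValues(expr)
  tot <- rowSums(v)
  sf <- ifelse(tot > 0, scale / tot, 0)
  ExpressionMatrix(log1p(v * sf), state = "normalized")
}

#' Full preprocessing pipeline
#'
#' Applies, in order: the per-section spot-count filter, the pooled
#' gene-presence filter on raw counts, per-spot normalization, and
#' highly-variable-gene selection on the normalized values; the final gene
#' panel is the intersection of the presence and HVG sets. Stage counts are
#' recorded in a provenance log.
#'
#' @param sections list of \linkS4class{STSection} carrying raw counts.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return list with elements \code{sections} (processed
#'   \linkS4class{STSection}s carrying a \code{logcounts} assay restricted to
#'   the retained genes), \code{genes} (retained gene names) and \code{log}
#'   (stage-by-stage spot/gene counts).
#' @export
runPreprocess <- function(sections, cfg = preprocessConfig()) {
  log <- list(input = list(sections = length(sections),
                           spots = sum(vapply(sections, ncol, integer(1))),
                           genes = nrow(sections[[1]])))
  sections <- filterSections(sections, cfg@minSpotsPerSection)
  log$after_section_filter <- list(sections = length(sections),
                                   spots = sum(vapply(sections, ncol, integer(1))))
  present <- filterGenes(sections, cfg@minSpotsPerGene)
  log$genes_present <- length(present)
  norm <- lapply(sections, function(s)
    normalizeCounts(sectionExpression(s, "counts"), cfg@scaleFactor))
  hvg <- selectHVG(norm, cfg@nHvg)
  log$genes_hvg <- length(hvg)
  genes <- intersect(present, hvg)
  log$genes_final <- length(genes)
  out <- mapply(function(s, nm) {
    SummarizedExperiment::assays(s)$logcounts <- t(exprValues(nm))
    s[genes, ]
  }, sections, norm, SIMPLIFY = FALSE)
  list(sections = out, genes = genes, log = log)
}
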