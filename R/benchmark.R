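#' Desk-scale synthetic recovery benchmark
#'
#' Generates the default synthetic study (or one from a supplied generator
#' configuration), runs the preprocessing pipeline with desk-scale
#' thresholds, trains the full model by leave-one-out cross-validation and
#' evaluates held-out per-gene correlation plus K-means spatial-domain
#' recovery against the generator's ground-truth annotations.
#'
#' @param synthCfg a \code{\link{synthConfig}}.
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param kDomains number of annotated spatial domains for clustering.
#' @param preprocess a \linkS4class{PreprocessConfig}; the default keeps the
#'   pipeline's structure at thresholds proportionate to a 64-spot section.
#' @param verbose print fold progress.
#' @return list: \code{report} (\linkS4class{EvalReport}), \code{predictions},
#'   \code{study} (sections + ground truth), \code{annotations}.
#' @export
syntheticBenchmark <- function(synthCfg = synthConfig(),
                               modelCfg = deskModelConfig(),
                               kDomains = 2L,
                               preprocess = preprocessConfig(
                                 minSpotsPerSection = 10, minSpotsPerGene = 5,
                                 nHvg = synthCfg$nGenes),
                               verbose = FALSE) {
  study <- makeSections(synthCfg)
  proc <- runPreprocess(study$sections, preprocess)
  ann <- lapply(study$groundTruth, makeAnnotation, k = kDomains)
  res <- trainLOOCV(proc$sections, modelCfg, annotations = ann,
                    verbose = verbose)
  res$study <- study
  res$annotations <- ann
  res$preprocessLog <- proc$log
  res
}
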