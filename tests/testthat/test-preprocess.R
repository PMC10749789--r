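# Section/gene filters and normalization.

mksection <- function(counts, id = "A") {
  n <- nrow(counts)
  side <- ceiling(sqrt(n))
  df <- data.frame(spot_id = paste0(id, seq_len(n)), section_id = id,
                   array_x = (seq_len(n) - 1L) %% side,
                   array_y = (seq_len(n) - 1L) %/% side,
                   pixel_x = 10 * ((seq_len(n) - 1L) %% side) + 5,
                   pixel_y = 10 * ((seq_len(n) - 1L) %/% side) + 5)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  rownames(counts) <- df$spot_id
  STSection(SpotTable(df), ExpressionMatrix(counts, "raw_counts"))
}

test_that("the section filter is strictly greater-than", {
  s181 <- mksection(matrix(1L, 181, 2), "A")
  s180 <- mksection(matrix(1L, 180, 2), "B")
  kept <- filterSections(list(s181, s180), minSpots = 180)
  expect_length(kept, 1L)
  expect_identical(sectionId(kept[[1]]), "A")
  expect_length(filterSections(list(s181), 10), 1L)   # all above: unchanged
  expect_warning(filterSections(list(s180), 500), "no section")
})

test_that("gene presence filter counts expressing spots pooled over sections", {
  # gene A nonzero in 3 of 5 spots, gene B in 1; threshold 2 keeps only A
  cnt <- cbind(A = c(1L, 0L, 2L, 0L, 5L), B = c(0L, 0L, 3L, 0L, 0L))
  s <- mksection(cnt)
  expect_identical(filterGenes(list(s), minSpots = 2), "A")
  expect_identical(filterGenes(list(s), minSpots = 0), c("A", "B"))
  cnt2 <- cbind(A = rep(1L, 5), B = rep(0L, 5))
  expect_identical(filterGenes(list(mksection(cnt2)), minSpots = 1), "A")
  # namespace mismatch
  s2 <- mksection(cbind(X = rep(1L, 5), B = rep(1L, 5)), "B")
  expect_error(filterGenes(list(s, s2), 1), "namespace")
  # monotone: raising the threshold never adds genes
  set.seed(2)
  s3 <- mksection(matrix(rpois(200, 0.5), 20), "C")
  prev <- filterGenes(list(s3), 0)
  for (th in 1:6) {
    cur <- filterGenes(list(s3), th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("HVG selection ranks by variance with lexicographic tie-break", {
  v <- cbind(g1 = c(0, 10, 5, 2), g2 = c(3, 3.5, 3.2, 3.3),
             g3 = c(0, 6, 3, 1))
  em <- ExpressionMatrix(v, "normalized")
  expect_identical(selectHVG(list(em), 2), c("g1", "g3"))
  expect_identical(selectHVG(list(em), 3), c("g1", "g2", "g3"))
  expect_warning(sel <- selectHVG(list(em), 10), "exceeds")
  expect_length(sel, 3L)
  # exact tie at the cutoff: smaller name wins
  v2 <- cbind(zz = c(0, 2), aa = c(0, 2), top = c(0, 9))
  expect_identical(selectHVG(list(ExpressionMatrix(v2, "normalized")), 2),
                   c("aa", "top"))
})

test_that("normalization matches direct arithmetic and handles zeros", {
  em <- ExpressionMatrix(matrix(c(10, 0, 90), 1, 3,
                                dimnames = list(NULL, c("a", "b", "c"))),
                         "raw_counts")
  out <- exprValues(normalizeCounts(em, scale = 1e6))
  expect_equal(as.vector(out), c(log1p(1e5), 0, log1p(9e5)), tolerance = 1e-12)
  expect_equal(as.vector(out), c(11.5129, 0, 13.7102), tolerance = 1e-4)
  z <- ExpressionMatrix(matrix(0L, 2, 2, dimnames = list(NULL, c("a", "b"))),
                        "raw_counts")
  expect_true(all(exprValues(normalizeCounts(z)) == 0))
  e2 <- ExpressionMatrix(matrix(c(1L, 1L), 1, dimnames = list(NULL, c("a", "b"))),
                         "raw_counts")
  expect_equal(as.vector(exprValues(normalizeCounts(e2, scale = 1))),
               rep(log(1.5), 2), tolerance = 1e-12)
})

test_that("normalization is invariant to per-spot library-size scaling", {
  set.seed(4)
  m <- matrix(rpois(40, 5) + 1L, 4, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  a <- exprValues(normalizeCounts(ExpressionMatrix(m, "raw_counts")))
  b <- exprValues(normalizeCounts(ExpressionMatrix(m * 7L, "raw_counts")))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the pipeline applies both gene filters and logs stage counts", {
  # 5 genes; g1/g2 expressed everywhere with high variance; g3 a single-spot
  # spike (huge log-scale variance but fails presence at threshold 3); g4 all
  # zero; g5 expressed everywhere but constant (fails the 3-gene HVG cut);
  # the final panel is the intersection of the presence and HVG sets
  set.seed(11)
  mk <- function(id) {
    m <- cbind(g1 = rpois(6, 20) + c(0L, 40L, 0L, 40L, 0L, 40L),
               g2 = rpois(6, 20) + c(40L, 0L, 40L, 0L, 40L, 0L),
               g3 = c(1L, 0L, 0L, 0L, 0L, 0L),
               g4 = rep(0L, 6),
               g5 = rep(5L, 6))
    mksection(m, id)
  }
  res <- runPreprocess(list(mk("A"), mk("B")),
                       preprocessConfig(minSpotsPerSection = 3,
                                        minSpotsPerGene = 3, nHvg = 3))
  expect_identical(res$genes, c("g1", "g2"))
  expect_identical(rownames(res$sections[[1]]), c("g1", "g2"))
  expect_true("logcounts" %in% names(SummarizedExperiment::assays(res$sections[[1]])))
  lg <- res$log
  expect_lte(lg$genes_final, lg$genes_hvg)
  expect_lte(lg$genes_final, lg$genes_present)
  expect_lte(lg$after_section_filter$spots, lg$input$spots)
})
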