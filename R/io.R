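#' @importFrom utils read.delim write.table head
NULL

#' Load a spot-by-gene count matrix
#'
#' Reads raw counts from a TSV/CSV table (genes as columns, spots as rows;
#' first column taken as spot identifiers when non-numeric) or from a
#' MatrixMarket file with gene/barcode sidecar files (MatrixMarket sources
#' follow the usual genes-as-rows convention and are transposed on load).
#'
#' @param path path to the counts file.
#' @param format \code{"tsv"} (tab- or comma-separated) or \code{"mtx"}.
#' @param transpose set \code{TRUE} when a TSV source stores genes as rows,
#'   or when an MTX source already stores spots as rows.
#' @param genesFile,barcodesFile sidecar paths for \code{format = "mtx"};
#'   default to \code{genes.tsv} / \code{barcodes.tsv} next to \code{path}.
#' @return An \linkS4class{ExpressionMatrix} with state \code{"raw_counts"}.
#' @export
loadCounts <- function(path, format = c("tsv", "mtx"), transpose = FALSE,
                       genesFile = file.path(dirname(path), "genes.tsv"),
                       barcodesFile = file.path(dirname(path), "barcodes.tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "tsv") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(read.delim(path, sep = sep, check.names = FALSE,
                              stringsAsFactors = FALSE),
                   error = function(e) stop("malformed counts file '", path,
                                            "': ", conditionMessage(e)))
    ids <- NULL
    if (ncol(df) >= 1 && !is.numeric(df[[1]])) {
      ids <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    }
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop("non-numeric count column(s): ", paste(names(df)[bad], collapse = ", "))
    m <- as.matrix(df)
    rownames(m) <- ids
    if (transpose) m <- t(m)
  } else {
    mm <- tryCatch(as.matrix(Matrix::readMM(path)),
                   error = function(e) stop("malformed MatrixMarket file '",
                                            path, "': ", conditionMessage(e)))
    genes <- if (file.exists(genesFile)) read.delim(genesFile, header = FALSE)[[1]]
             else paste0("gene", seq_len(nrow(mm)))
    bcs <- if (file.exists(barcodesFile)) read.delim(barcodesFile, header = FALSE)[[1]]
           else paste0("spot", seq_len(ncol(mm)))
    rownames(mm) <- as.character(genes)
    colnames(mm) <- as.character(bcs)
    m <- if (transpose) mm else t(mm)
  }
  if (anyNA(m)) {
    ij <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable count at row %d, column %d", ij[1], ij[2]))
  }
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d ('%s'), column %d",
                 ij[1], rownames(m)[ij[1]] %||% "", ij[2]))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("gene", seq_len(ncol(m)))
  ExpressionMatrix(m, state = "raw_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a counts or prediction matrix as TSV
#'
#' Spots as rows, genes as columns, spot identifiers in the first column.
#' \code{loadCounts} reads the result back unchanged.
#'
#' @param expr an \linkS4class{ExpressionMatrix} or plain matrix.
#' @param path output path.
#' @export
writeCountsTsv <- function(expr, path) {
  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  df <- data.frame(spot_id = rownames(m) %||% paste0("spot", seq_len(nrow(m))),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a spot table
#'
#' @param path TSV/CSV file with one row per spot.
#' @param columns named character vector mapping the canonical fields
#'   \code{spot_id}, \code{section_id}, \code{array_x}, \code{array_y},
#'   \code{pixel_x}, \code{pixel_y} to the column names used in the file.
#'   A missing \code{section_id} column is filled with \code{"section1"}.
#' @return A \linkS4class{SpotTable}, rows in file order.
#' @export
loadSpots <- function(path, columns = c(spot_id = "spot_id",
                                        section_id = "section_id",
                                        array_x = "array_x", array_y = "array_y",
                                        pixel_x = "pixel_x", pixel_y = "pixel_y")) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  out <- list()
  for (field in c("spot_id", "section_id", "array_x", "array_y", "pixel_x", "pixel_y")) {
    src <- columns[[field]] %||% field
    if (!src %in% names(df)) {
      if (field == "section_id") { out[[field]] <- "section1"; next }
      stop("spot table is missing column '", src, "' (field ", field, ")")
    }
    out[[field]] <- df[[src]]
  }
  for (field in c("array_x", "array_y", "pixel_x", "pixel_y"))
    if (!is.numeric(out[[field]]))
      stop("column for ", field, " is not numeric")
  SpotTable(data.frame(out, stringsAsFactors = FALSE))
}

#' Load a slide image
#'
#' Reads PNG or TIFF into an H x W x 3 array in [0, 1]. Grayscale images are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path image path (.png, .tif/.tiff).
#' @return numeric array H x W x 3.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
         else stop("unsupported image format (PNG and TIFF are supported): ", path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Cut per-spot patches from a slide image
#'
#' Each patch is centred at \code{(round(pixel_x), round(pixel_y))} using
#' 0-based pixel coordinates with (0, 0) at the image's top-left corner: a
#' patch of size S covers pixel rows \code{[cy - floor(S/2), cy + ceiling(S/2))}
#' and likewise for columns (half-open). Patches overlapping the image border
#' are zero-padded to full size; intensities are returned in [0, 1].
#'
#' @param image H x W x 3 array in [0, 1] (values in 0..255 are rescaled).
#' @param spots a \linkS4class{SpotTable}.
#' @param patchSize patch side length in pixels (default 112, matching the
#'   spot diameter of the spatial transcriptomics arrays this model targets).
#' @return A \linkS4class{PatchStack} with one patch per spot, in spot order.
#' @export
extractPatches <- function(image, spots, patchSize = 112L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (max(image) > 1) image <- image / 255
  df <- spotTable(spots)
  H <- dim(image)[1]; W <- dim(image)[2]
  cx <- round(df$pixel_x); cy <- round(df$pixel_y)
  out <- cx < 0 | cx > W - 1 | cy < 0 | cy > H - 1
  if (any(out))
    stop("spot centre outside image for spot(s): ",
         paste(df$spot_id[out], collapse = ", "))
  S <- as.integer(patchSize)
  lo <- S %/% 2L; hi <- S - lo            # [c - lo, c + hi)
  N <- nrow(df)
  patches <- array(0, c(N, 3L, S, S))
  for (i in seq_len(N)) {
    r0 <- cy[i] - lo; c0 <- cx[i] - lo    # 0-based patch origin
    rr <- max(r0, 0L):min(r0 + S - 1L, H - 1L)
    cc <- max(c0, 0L):min(c0 + S - 1L, W - 1L)
    block <- image[rr + 1L, cc + 1L, , drop = FALSE]
    patches[i, , (rr - r0) + 1L, (cc - c0) + 1L] <-
      aperm(block, c(3L, 1L, 2L))
  }
  new("PatchStack", patches = patches, spotIds = as.character(df$spot_id))
}

#' Export a spot graph as an edge-list TSV
#'
#' @param graph a \linkS4class{SpotGraph}.
#' @param path output path.
#' @export
writeGraphTsv <- function(graph, path) {
  write.table(graphEdges(graph), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
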