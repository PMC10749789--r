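# Synthetic spatial-transcriptomics sections with a known image-to-expression
# signal path. A smooth per-section density field drives (i) where nuclei-like
# blobs are painted on the slide and (ii) a low-rank latent program whose
# loadings generate negative-binomial counts, so that a model reading local
# nuclear texture from the image patches has a well-defined signal to recover.

#' Synthetic-data configuration
#'
#' Defaults define the desk-scale benchmark: 4 sections of 8 x 8 spots spaced
#' 56 pixels on a 448 x 448 slide, 20 genes, 3 latent programs, strong
#' image-to-expression signal.
#'
#' @param nSections number of sections.
#' @param gridRows,gridCols spot array shape.
#' @param spotSpacing centre-to-centre spot distance in pixels; spot (0, 0)
#'   sits at pixel (spacing/2, spacing/2).
#' @param nGenes gene panel size.
#' @param nPrograms number of latent expression programs derived from the
#'   density field.
#' @param nBlobs nuclei-like blobs painted per section (placed by rejection
#'   sampling against the density field).
#' @param blobSd Gaussian radius of a blob, pixels.
#' @param beta signal strength: scales the latent programs in the log-mean of
#'   expression. \code{beta = 0} severs the image-expression link (null data).
#' @param rho spatial autocorrelation length of the latent programs, in units
#'   of spot spacing (Gaussian kernel smoothing over the spot grid).
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param baseMean baseline mean count per gene per spot.
#' @param seed integer seed; each section derives its own substream.
#' @return a classed list of generator settings.
#' @export
synthConfig <- function(nSections = 4L, gridRows = 8L, gridCols = 8L,
                        spotSpacing = 56L, nGenes = 20L, nPrograms = 3L,
                        nBlobs = 1500L, blobSd = 3, beta = 1.5, rho = 1,
                        dispersion = 15, baseMean = 30, seed = 0L) {
  cfg <- list(nSections = nSections, gridRows = gridRows, gridCols = gridCols,
              spotSpacing = spotSpacing, nGenes = nGenes, nPrograms = nPrograms,
              nBlobs = nBlobs, blobSd = blobSd, beta = beta, rho = rho,
              dispersion = dispersion, baseMean = baseMean, seed = as.integer(seed))
  stopifnot(nSections >= 1, gridRows >= 2, gridCols >= 2, nGenes >= 1,
            nPrograms >= 1, dispersion > 0, baseMean > 0, rho > 0)
  class(cfg) <- "synthConfig"
  cfg
}

# density field in [0, 1] on an H x W grid: a fixed low-frequency gradient
# plus random cosine waves, pushed through a logistic contrast so the tissue
# falls into two well-separated density plateaus (dense- and sparse-nuclei
# domains) with smooth boundaries -- the spatial domains the clustering
# benchmark asks a model to recover
.density_field <- function(H, W, nwaves = 3L, contrast = 0.4) {
  xs <- (seq_len(W) - 0.5) / W
  ys <- (seq_len(H) - 0.5) / H
  X <- matrix(rep(xs, each = H), H, W)
  Y <- matrix(rep(ys, times = W), H, W)
  F <- 0.8 * X                         # large-scale left-right gradient
  for (q in seq_len(nwaves)) {
    f <- stats::runif(2, 0.3, 0.9) * sample(c(-1, 1), 2, replace = TRUE)
    ph <- stats::runif(1, 0, 2 * pi)
    F <- F + stats::runif(1, 0.3, 0.6) * cos(2 * pi * (f[1] * X + f[2] * Y) + ph)
  }
  F <- (F - stats::median(F)) / stats::sd(F)
  1 / (1 + exp(-F / contrast))
}

# paint gaussian "nuclei" on an H&E-like background; returns H x W x 3
.paint_blobs <- function(D, nBlobs, blobSd) {
  H <- nrow(D); W <- ncol(D)
  bg <- c(0.91, 0.78, 0.87)            # eosin-pink background
  fg <- c(0.38, 0.22, 0.52)            # hematoxylin-purple nuclei
  img <- array(rep(bg, each = H * W), c(H, W, 3))
  # rejection-sample blob centres against the density field
  n_cand <- nBlobs * 4L
  cx <- stats::runif(n_cand, 1, W)
  cy <- stats::runif(n_cand, 1, H)
  keep <- stats::runif(n_cand) < D[cbind(ceiling(cy), ceiling(cx))]
  cx <- head(cx[keep], nBlobs); cy <- head(cy[keep], nBlobs)
  r <- ceiling(3 * blobSd)
  mask <- matrix(0, H, W)
  for (b in seq_along(cx)) {
    rr <- max(1, floor(cy[b] - r)):min(H, ceiling(cy[b] + r))
    cc <- max(1, floor(cx[b] - r)):min(W, ceiling(cx[b] + r))
    g <- exp(-(outer((rr - cy[b])^2, (cc - cx[b])^2, "+")) / (2 * blobSd^2))
    mask[rr, cc] <- mask[rr, cc] + g
  }
  mask <- pmin(mask, 1)
  for (ch in 1:3) img[, , ch] <- bg[ch] + (fg[ch] - bg[ch]) * mask
  img
}

#' Generate one synthetic section
#'
#' Renders the slide image, places spots on the array grid, derives latent
#' programs from the density field at the spot locations (smoothed with
#' correlation length \code{rho}), and draws negative-binomial counts with
#' mean \eqn{\mu = baseMean \cdot \exp(\beta \, z L^T)}.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param sectionIndex 1-based section number (fixes the per-section seed).
#' @return list with \code{section} (an \linkS4class{STSection} with image and
#'   raw counts) and \code{groundTruth} (density at spots \code{D}, latent
#'   programs \code{z}, loadings \code{L}, log-mean \code{eta}, mean
#'   \code{mu}).
#' @export
makeSection <- function(cfg, sectionIndex = 1L) {
  H <- cfg$gridRows * cfg$spotSpacing
  W <- cfg$gridCols * cfg$spotSpacing
  set.seed(cfg$seed * 1009L + sectionIndex)
  D <- .density_field(H, W)
  img <- .paint_blobs(D, cfg$nBlobs, cfg$blobSd)

  gx <- rep(0:(cfg$gridCols - 1L), times = cfg$gridRows)
  gy <- rep(0:(cfg$gridRows - 1L), each = cfg$gridCols)
  px <- (gx + 0.5) * cfg$spotSpacing
  py <- (gy + 0.5) * cfg$spotSpacing
  if (any(px > W - 1) || any(py > H - 1))
    stop("spot grid does not fit inside the image at this spacing")
  sid <- sprintf("s%dx%d", gy, gx)
  spots <- SpotTable(data.frame(
    spot_id = sid, section_id = sprintf("sec%d", sectionIndex),
    array_x = gx, array_y = gy, pixel_x = px, pixel_y = py,
    stringsAsFactors = FALSE))

  # local nuclear density at each spot: mean of D over a half-spacing window
  # (small enough not to smear the domain plateaus across boundaries)
  half <- cfg$spotSpacing %/% 4L
  Ds <- vapply(seq_along(px), function(i) {
    rr <- max(1, py[i] - half):min(H, py[i] + half)
    cc <- max(1, px[i] - half):min(W, px[i] + half)
    mean(D[rr, cc])
  }, numeric(1))

  # latent programs: fixed nonlinear features of the density, spatially
  # smoothed with a gaussian kernel of width rho (in spot-spacing units)
  zraw <- cbind(Ds, Ds^2, cos(pi * Ds))[, seq_len(cfg$nPrograms), drop = FALSE]
  d2 <- as.matrix(stats::dist(cbind(gx, gy)))^2
  K <- exp(-d2 / (2 * cfg$rho^2))
  K <- K / rowSums(K)
  z <- K %*% scale(zraw)
  z <- scale(z)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL

  set.seed(cfg$seed * 1009L + 500L)    # loadings shared across sections
  L <- matrix(stats::rnorm(cfg$nGenes * cfg$nPrograms), cfg$nGenes) /
    sqrt(cfg$nPrograms)
  set.seed(cfg$seed * 1009L + sectionIndex + 250L)
  eta <- pmin(pmax(cfg$beta * z %*% t(L), -3), 3)
  mu <- cfg$baseMean * exp(eta)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = cfg$dispersion), nrow(mu))
  dimnames(counts) <- list(sid, sprintf("gene%02d", seq_len(cfg$nGenes)))
  expr <- ExpressionMatrix(counts, state = "raw_counts")
  list(section = STSection(spots, expr, image = img),
       groundTruth = list(D = Ds, z = z, L = L, eta = eta, mu = mu))
}

#' Generate a full synthetic study
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list with \code{sections} (list of \linkS4class{STSection}) and
#'   \code{groundTruth} (per-section lists from \code{\link{makeSection}}).
#' @export
makeSections <- function(cfg = synthConfig()) {
  out <- lapply(seq_len(cfg$nSections), function(i) makeSection(cfg, i))
  list(sections = lapply(out, `[[`, "section"),
       groundTruth = lapply(out, `[[`, "groundTruth"))
}

#' Spatial-domain annotation from the generator's ground truth
#'
#' Quantile-bins the latent density field at the spot locations into k
#' domains; stands in for expert spatial-domain annotations when evaluating
#' clustering of predicted expression.
#'
#' @param groundTruth one section's ground truth from \code{\link{makeSection}}.
#' @param k number of domains (>= 2).
#' @return integer partition labels, one per spot.
#' @export
makeAnnotation <- function(groundTruth, k = 2L) {
  if (k < 2L) stop("k must be at least 2")
  d <- groundTruth$D
  qs <- stats::quantile(d, probs = seq(0, 1, length.out = k + 1L))
  qs[1] <- -Inf; qs[k + 1L] <- Inf
  as.integer(cut(d, qs, labels = FALSE))
}

#' Write a synthetic section in the formats the readers consume
#'
#' PNG slide image, TSV spot table and TSV counts under \code{dir}, named
#' \code{<sectionId>.{png,spots.tsv,counts.tsv}}.
#'
#' @param section an \linkS4class{STSection} with an image.
#' @param dir output directory (created if missing).
#' @return the three file paths, invisibly.
#' @export
writeSection <- function(section, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- sectionId(section)
  pimg <- file.path(dir, paste0(id, ".png"))
  png::writePNG(slideImage(section), pimg)
  pspot <- file.path(dir, paste0(id, ".spots.tsv"))
  write.table(spotTable(section), pspot, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pcnt <- file.path(dir, paste0(id, ".counts.tsv"))
  writeCountsTsv(sectionExpression(section, "counts"), pcnt)
  invisible(c(image = pimg, spots = pspot, counts = pcnt))
}
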