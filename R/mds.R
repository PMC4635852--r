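#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2/2` and takes the top-`d` eigenvectors scaled by the
#' square root of their eigenvalues. If a retained eigenvalue is negative
#' (the distances are not d-embeddable), the corresponding axis is set to
#' zero with a warning.
#'
#' @param d a symmetric, non-negative distance matrix with zero diagonal, or
#'   a [stats::dist] object.
#' @param k embedding dimension (default 2).
#' @return samples-by-k coordinate matrix (row names preserved).
#' @export
classicalMDS <- function(d, k = 2) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (k < 1 || k > n) stop("embedding dimension out of range")
  # J (-D^2/2) J via sequential row/column centering
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  eig <- eigen(B, symmetric = TRUE)
  lambda <- eig$values[seq_len(k)]
  neg <- lambda < -1e-12 * max(abs(eig$values), 1)
  if (any(neg))
    warning(sum(neg), " retained eigenvalue(s) negative; axes set to zero")
  lambda[lambda < 0] <- 0
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lambda), k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("dim", seq_len(k))
  coords
}

#' Flag outlier samples by intracentroid distance z-score
#'
#' Computes each sample's Euclidean distance to a center (medoid by default:
#' the sample minimizing the summed distance to all others; or the
#' coordinate-wise centroid), standardizes the distances and flags samples
#' whose z-score exceeds the threshold. Flagging is a single pass; the
#' embedding is not recomputed after removal.
#'
#' @param coordinates samples-by-d numeric matrix (e.g. from
#'   [classicalMDS()]), row names = sample IDs.
#' @param centerMode `"medoid"` (default) or `"centroid"`.
#' @param zThreshold flag samples with distance z-score above this value
#'   (default 2).
#' @return an [EmbeddingReport-class].
#' @export
flagOutliers <- function(coordinates, centerMode = c("medoid", "centroid"),
                         zThreshold = 2) {
  centerMode <- match.arg(centerMode)
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (n < 4) stop("need at least 4 samples to flag outliers")
  if (is.null(rownames(coordinates)))
    rownames(coordinates) <- paste0("S", seq_len(n))
  if (centerMode == "medoid") {
    D <- as.matrix(stats::dist(coordinates))
    center <- coordinates[which.min(rowSums(D)), ]
  } else {
    center <- colMeans(coordinates)
  }
  dists <- sqrt(rowSums(sweep(coordinates, 2, center)^2))
  sdd <- stats::sd(dists)
  degenerate <- !is.finite(sdd) || sdd == 0
  z <- if (degenerate) rep(0, n) else (dists - mean(dists)) / sdd
  names(z) <- rownames(coordinates)
  out <- names(z)[z > zThreshold]
  new("EmbeddingReport", coordinates = coordinates, center = as.numeric(center),
      centerMode = centerMode, distances = stats::setNames(dists, names(z)),
      zscores = z, outliers = out, zThreshold = zThreshold,
      degenerate = degenerate)
}

#' Embed samples and flag outliers in one step
#'
#' Convenience wrapper: Euclidean distances between sample columns of the
#' (typically z-scored, filtered) expression matrix, classical MDS, then
#' [flagOutliers()].
#'
#' @param x an [ExpressionMatrix-class] or genes-by-samples matrix.
#' @param k embedding dimension (default 2).
#' @inheritParams flagOutliers
#' @return an [EmbeddingReport-class].
#' @export
detectOutlierSamples <- function(x, k = 2, centerMode = "medoid",
                                 zThreshold = 2) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  d <- stats::dist(t(v))
  flagOutliers(classicalMDS(d, k), centerMode = centerMode,
               zThreshold = zThreshold)
}

#' Export an EmbeddingReport as a TSV table
#'
#' Columns: sample, one per embedding dimension, distance, zscore, outlier.
#'
#' @param report an [EmbeddingReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEmbeddingTSV <- function(report, path) {
  co <- report@coordinates
  out <- data.frame(sample = rownames(co), signif(co, 6),
                    distance = signif(report@distances, 6),
                    zscore = signif(report@zscores, 6),
                    outlier = rownames(co) %in% report@outliers)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
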