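#' Per-gene z-score normalization
#'
#' Centers and scales every gene row to mean 0 and sample sd 1 (n-1
#' denominator). Row and column order are unchanged. Genes with zero
#' variance cannot be scaled and raise an error naming them; drop or filter
#' such genes first.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix (genes x samples).
#' @return an object of the same class with normalized values.
#' @export
zscoreNormalize <- function(x) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    stop("zero-variance gene rows cannot be z-scored: ",
         paste(utils::head(rownames(v)[zero], 5), collapse = ", "),
         if (sum(zero) > 5) sprintf(" (and %d more)", sum(zero) - 5) else "")
  z <- (v - mu) / sdv
  if (is(x, "ExpressionMatrix")) ExpressionMatrix(z, sampleGroups(x)) else z
}

#' Per-gene summary statistics for expression filtering
#'
#' Computed on the original (log2) scale, before z-scoring: mean, sample sd,
#' coefficient of variation `cv = sd/mean`, and `scaledMean` = the per-gene
#' mean min-max scaled across genes to `[0, 1]`. Genes with mean <= 0 get
#' `cv = NA` (they cannot pass a CV filter).
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix (genes x samples).
#' @return data.frame with columns `gene`, `mean`, `sd`, `cv`, `scaledMean`.
#' @export
geneStats <- function(x) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  rng <- range(mu)
  scaled <- if (diff(rng) > 0) (mu - rng[1]) / diff(rng) else rep(0, length(mu))
  data.frame(gene = rownames(v), mean = mu, sd = sdv, cv = cv,
             scaledMean = scaled, row.names = NULL)
}

#' Filter genes on scaled expression level and coefficient of variation
#'
#' Retains genes with `scaledMean > scaledMin` AND `cv > cvMin` (strict
#' inequalities), the high-expression/high-variability filter applied before
#' subtype discovery. Defaults: both thresholds 0.12.
#'
#' @param x an [ExpressionMatrix-class].
#' @param scaledMin minimum scaled expression level (min-max scaled per-gene
#'   mean), default 0.12.
#' @param cvMin minimum coefficient of variation, default 0.12.
#' @return list with elements `matrix` (the filtered
#'   [ExpressionMatrix-class]) and `report` (data.frame: the [geneStats()]
#'   columns plus logical `passExpression`, `passCV`, `retained`, and
#'   attributes `nInput`/`nRetained`).
#' @export
filterGenes <- function(x, scaledMin = 0.12, cvMin = 0.12) {
  stopifnot(scaledMin >= 0, cvMin >= 0)
  st <- geneStats(x)
  # a zero threshold disables its criterion (strict '>' would always drop
  # the minimum-mean gene through min-max scaling)
  st$passExpression <- if (scaledMin <= 0) rep(TRUE, nrow(st)) else
    st$scaledMean > scaledMin
  st$passCV <- if (cvMin <= 0) !is.na(st$cv) else
    !is.na(st$cv) & st$cv > cvMin
  st$retained <- st$passExpression & st$passCV
  if (!any(st$retained))
    stop("no genes pass the filter (scaledMin=", scaledMin, ", cvMin=", cvMin,
         "); lower the thresholds")
  v <- exprValues(x)[st$retained, , drop = FALSE]
  out <- ExpressionMatrix(v, sampleGroups(x))
  attr(st, "nInput") <- nrow(st)
  attr(st, "nRetained") <- sum(st$retained)
  list(matrix = out, report = st)
}
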