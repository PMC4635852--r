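#' Row-wise two-group t statistics
#'
#' Student's (pooled-variance) two-sample t test per gene row, two-sided;
#' Welch available by flag. Degenerate rows are handled explicitly: zero
#' variance in both groups with equal means gives `t = 0, p = 1`; zero
#' variance with unequal means is infinite separation and gives the `p = 0`
#' sentinel with `degenerate = TRUE`.
#'
#' @param x genes-by-samples numeric matrix or [ExpressionMatrix-class].
#' @param labels character/factor of length `ncol(x)`; exactly two distinct
#'   labels must be present, and group1 is the first label encountered.
#' @param varianceMode `"pooled"` (default) or `"welch"`.
#' @return data.frame: `gene`, `mean1`, `mean2`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
tTestTwoGroup <- function(x, labels, varianceMode = c("pooled", "welch")) {
  varianceMode <- match.arg(varianceMode)
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != ncol(v)) stop("labels must match the sample columns")
  grp <- unique(labels)
  if (length(grp) != 2) stop("exactly two groups required, got ", length(grp))
  i1 <- labels == grp[1]; i2 <- labels == grp[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  v1 <- rowSums((v[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((v[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  if (varianceMode == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  diff <- m1 - m2
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  equal <- degenerate & diff == 0
  tstat[equal] <- 0; p[equal] <- 1
  sep <- degenerate & diff != 0
  tstat[sep] <- sign(diff[sep]) * Inf; p[sep] <- 0
  df[degenerate & !is.finite(df)] <- NA_real_
  data.frame(gene = rownames(v), mean1 = m1, mean2 = m2, t = tstat, df = df,
             p = p, degenerate = degenerate & diff != 0, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order (monotone in p-value rank, clipped at 1).
#' @export
bhFDR <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression with FDR control
#'
#' Runs [tTestTwoGroup()] on the two requested groups, attaches BH q-values
#' and calls genes significant at `q < alpha` (or `p < alpha` with
#' `gate = "p"`). Direction is `up` when group1's mean exceeds group2's.
#'
#' @param x genes-by-samples matrix or [ExpressionMatrix-class].
#' @param labels per-sample group labels (defaults to `sampleGroups(x)` for
#'   an ExpressionMatrix).
#' @param group1,group2 the two labels to contrast; samples with other
#'   labels are ignored. Default: the first two distinct labels.
#' @param alpha significance cutoff, default 0.05.
#' @param gate `"q"` (default, FDR-gated) or `"p"`.
#' @param varianceMode passed to [tTestTwoGroup()].
#' @return a [DEResult-class].
#' @export
differentialGenes <- function(x, labels = NULL, group1 = NULL, group2 = NULL,
                              alpha = 0.05, gate = c("q", "p"),
                              varianceMode = "pooled") {
  gate <- match.arg(gate)
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (is.null(labels)) {
    if (!is(x, "ExpressionMatrix"))
      stop("'labels' required for a plain matrix")
    labels <- sampleGroups(x)
  }
  labels <- as.character(labels)
  lev <- unique(labels)
  if (is.null(group1)) group1 <- lev[1]
  if (is.null(group2)) group2 <- setdiff(lev, group1)[1]
  keep <- labels %in% c(group1, group2)
  sub <- v[, keep, drop = FALSE]
  sublab <- labels[keep]
  # fix group order so group1 is first regardless of column order
  ord <- order(match(sublab, c(group1, group2)))
  tt <- tTestTwoGroup(sub[, ord, drop = FALSE], sublab[ord], varianceMode)
  tt$q <- bhFDR(tt$p)
  tt$direction <- ifelse(tt$mean1 >= tt$mean2, "up", "down")
  sig <- if (gate == "q") tt$gene[tt$q < alpha] else tt$gene[tt$p < alpha]
  new("DEResult", table = tt, groups = c(group1, group2), alpha = alpha,
      gate = gate, significant = as.character(sig))
}

#' Partition differential genes into core and subtype-unique sets
#'
#' Set algebra over the two subtype-vs-control significant sets:
#' core = both, uniqueA = only A, uniqueB = only B.
#'
#' @param deA,deB [DEResult-class] objects (or plain character vectors of
#'   significant gene IDs) for subtype A vs control and subtype B vs
#'   control, over the same gene universe.
#' @return a [GenePartition-class].
#' @export
partitionGenes <- function(deA, deB) {
  a <- if (is(deA, "DEResult")) significantGenes(deA) else as.character(deA)
  b <- if (is(deB, "DEResult")) significantGenes(deB) else as.character(deB)
  new("GenePartition",
      core = intersect(a, b),
      uniqueA = setdiff(a, b),
      uniqueB = setdiff(b, a))
}

#' Write a DEResult table as TSV
#'
#' @param x a [DEResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDETSV <- function(x, path) {
  tab <- x@table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
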