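#' Agglomerative hierarchical clustering of samples
#'
#' Clusters the sample columns with [stats::hclust]. Default distance is
#' `one_minus_pearson` (1 - Pearson correlation between sample profiles),
#' the usual choice for expression heatmaps; default linkage is average.
#'
#' @param x an [ExpressionMatrix-class] or genes-by-samples matrix (z-scored
#'   values recommended).
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (ward.D2).
#' @return a list with elements `tree` ([stats::hclust]) and `dist`
#'   (the [stats::dist] used, needed by the validity indices).
#' @export
hierarchicalCluster <- function(x,
                                distance = c("one_minus_pearson", "euclidean"),
                                linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (ncol(v) < 2) stop("need at least 2 samples to cluster")
  d <- switch(distance,
    euclidean = stats::dist(t(v)),
    one_minus_pearson = stats::as.dist(1 - stats::cor(v)))
  if (any(!is.finite(d))) stop("non-finite sample distances")
  method <- if (linkage == "ward") "ward.D2" else linkage
  list(tree = stats::hclust(d, method = method), dist = d)
}

#' Cut a merge tree into k clusters with stable labels
#'
#' Wraps [stats::cutree] and renumbers clusters by order of first
#' appearance, so cluster 1 is the cluster containing the first sample.
#'
#' @param tree a [stats::hclust] object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster labels in `1..k`.
#' @export
cutTreeK <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  lab <- stats::cutree(tree, k = k)
  relabelByAppearance(lab)
}

relabelByAppearance <- function(lab) {
  first <- unique(lab)
  out <- match(lab, first)
  names(out) <- names(lab)
  out
}

#' Connectivity index of a clustering
#'
#' For each sample, its `L` nearest neighbors (ties broken by sample order)
#' contribute `1/j` for the `j`-th neighbor whenever that neighbor is
#' assigned to a different cluster. Lower is better; 0 means every near
#' neighborhood is co-clustered.
#'
#' @param d distance matrix or [stats::dist] over samples.
#' @param labels integer cluster labels.
#' @param L neighborhood size (default 10, capped at n-1).
#' @return non-negative scalar.
#' @export
connectivityIndex <- function(d, labels, L = 10) {
  D <- as.matrix(d)
  n <- nrow(D)
  L <- min(L, n - 1L)
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])           # stable: ties by sample order
    nb <- (seq_len(n)[-i])[ord][seq_len(L)]
    total <- total + sum((labels[nb] != labels[i]) / seq_len(L))
  }
  total
}

#' Dunn index of a clustering
#'
#' Minimum between-cluster (single-linkage) distance divided by the maximum
#' within-cluster diameter; higher is better. When every cluster is a
#' singleton the maximum diameter is 0 and the index is `Inf`.
#'
#' @inheritParams connectivityIndex
#' @return positive scalar (possibly `Inf`).
#' @export
dunnIndex <- function(d, labels) {
  D <- as.matrix(d)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least 2 clusters")
  minInter <- Inf
  maxDiam <- 0
  for (a in seq_along(cl)) {
    ia <- which(labels == cl[a])
    if (length(ia) > 1)
      maxDiam <- max(maxDiam, max(D[ia, ia]))
    for (b in seq_along(cl)) {
      if (b <= a) next
      ib <- which(labels == cl[b])
      minInter <- min(minInter, min(D[ia, ib, drop = FALSE]))
    }
  }
  if (maxDiam == 0) return(Inf)
  minInter / maxDiam
}

#' Mean silhouette width of a clustering
#'
#' Per sample: `a` = mean distance to its own cluster (excluding itself),
#' `b` = smallest mean distance to another cluster; silhouette =
#' `(b - a)/max(a, b)`. Singleton samples get 0. Returns the mean over
#' samples, in `[-1, 1]`.
#'
#' @inheritParams connectivityIndex
#' @return scalar in `[-1, 1]`.
#' @export
silhouetteIndex <- function(d, labels) {
  D <- as.matrix(d)
  n <- nrow(D)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(cl[cl != labels[i]], function(cc)
      mean(D[i, which(labels == cc)]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of clusters by validity-index vote
#'
#' Evaluates every `k` in `kRange`: labels from [cutTreeK()], then
#' connectivity (best = minimum), Dunn and silhouette (best = maximum).
#' Each index votes for its best k; the majority wins, with ties broken
#' toward the smallest k among the most-voted.
#'
#' @param d distance matrix or [stats::dist] over samples (the one used to
#'   build the tree).
#' @param tree a [stats::hclust] object.
#' @param kRange candidate cluster counts (default 2:6, truncated to n-1).
#' @param L connectivity neighborhood size (default 10).
#' @return a [ClusterSolution-class].
#' @export
selectK <- function(d, tree, kRange = 2:6, L = 10) {
  n <- length(tree$order)
  kRange <- sort(unique(as.integer(kRange)))
  kRange <- kRange[kRange >= 2 & kRange <= n]
  if (!length(kRange)) stop("empty k range")
  labs <- vapply(kRange, function(k) cutTreeK(tree, k), integer(n))
  rownames(labs) <- tree$labels %||% paste0("S", seq_len(n))
  colnames(labs) <- kRange
  idx <- data.frame(
    k = kRange,
    connectivity = vapply(seq_along(kRange), function(j)
      connectivityIndex(d, labs[, j], L = L), 0),
    dunn = vapply(seq_along(kRange), function(j)
      dunnIndex(d, labs[, j]), 0),
    silhouette = vapply(seq_along(kRange), function(j)
      silhouetteIndex(d, labs[, j]), 0))
  votes <- c(connectivity = kRange[which.min(idx$connectivity)],
             dunn = kRange[which.max(idx$dunn)],
             silhouette = kRange[which.max(idx$silhouette)])
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  new("ClusterSolution", tree = tree, labelsByK = labs, indices = idx,
      votes = as.integer(votes) |> stats::setNames(names(votes)),
      selectedK = min(winners))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
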