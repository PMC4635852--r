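# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they check.

bruteConnectivity <- function(D, labels, L) {
  D <- as.matrix(D)
  n <- nrow(D)
  L <- min(L, n - 1)
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # selection sort with ties by index, to pin down the tie rule explicitly
    remaining <- others
    for (j in seq_len(L)) {
      best <- remaining[1]
      for (m in remaining) if (D[i, m] < D[i, best]) best <- m
      if (labels[best] != labels[i]) total <- total + 1 / j
      remaining <- setdiff(remaining, best)
    }
  }
  total
}

bruteDunn <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  inter <- Inf
  diam <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (labels[i] == labels[j]) diam <- max(diam, D[i, j])
    else inter <- min(inter, D[i, j])
  }
  if (diam == 0) Inf else inter / diam
}

bruteSilhouette <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive enumeration of draws of size nInput from a universe with nSet
# marked elements; P[overlap >= k]
bruteHypergeom <- function(nUniverse, nSet, nInput, k) {
  hits <- 0
  tot <- 0
  for (draw in utils::combn(nUniverse, nInput, simplify = FALSE)) {
    tot <- tot + 1
    if (sum(draw <= nSet) >= k) hits <- hits + 1
  }
  hits / tot
}

# literal step-up definition: q_(i) = min_{j >= i} (m p_(j) / j), capped at 1
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

randomClustering <- function(n, kMax = 4) {
  pts <- matrix(rnorm(n * 3), n, 3)
  k <- sample(2:min(kMax, n - 1), 1)
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  list(D = as.matrix(dist(pts)), labels = labels)
}

ariIndex <- function(a, b) mclust::adjustedRandIndex(a, b)

# small labelled expression fixture
makeExpr <- function(values, groups = NULL) {
  ExpressionMatrix(values, groups)
}
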