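sepPairs <- function() {
  # two tight pairs far apart, genes x samples
  v <- cbind(s1 = c(0, 0, 0), s2 = c(0.1, 0, 0),
             s3 = c(10, 10, 10), s4 = c(10.1, 10, 10))
  rownames(v) <- paste0("g", 1:3)
  v
}

test_that("hierarchical clustering joins well-separated pairs first", {
  hc <- hierarchicalCluster(sepPairs(), distance = "euclidean")
  merges <- hc$tree$merge
  # first two merges join the planted pairs (singleton-singleton merges,
  # in either order: the two pair distances tie)
  expect_true(all(merges[1:2, ] < 0))
  j1 <- sort(abs(merges[1, ])); j2 <- sort(abs(merges[2, ]))
  expect_true((all(j1 == c(1, 2)) && all(j2 == c(3, 4))) ||
              (all(j1 == c(3, 4)) && all(j2 == c(1, 2))))
  lab <- cutTreeK(hc$tree, 2)
  expect_identical(unname(lab), c(1L, 1L, 2L, 2L))
})

test_that("average-linkage merge heights are monotone on random data", {
  set.seed(14)
  for (rep in 1:100) {
    v <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    hc <- hierarchicalCluster(v, distance = "euclidean", linkage = "average")
    expect_true(all(diff(hc$tree$height) >= -1e-12))
  }
})

test_that("non-finite distances are rejected", {
  v <- cbind(s1 = c(1, 1), s2 = c(1, 1), s3 = c(2, 2))  # zero-variance pair
  rownames(v) <- c("g1", "g2")
  expect_error(suppressWarnings(
    hierarchicalCluster(v, distance = "one_minus_pearson")), "non-finite")
})

test_that("cutTreeK covers the k range with stable labels", {
  hc <- hierarchicalCluster(sepPairs(), distance = "euclidean")
  expect_identical(unname(cutTreeK(hc$tree, 1)), rep(1L, 4))
  expect_identical(unname(cutTreeK(hc$tree, 4)), 1:4)
  expect_error(cutTreeK(hc$tree, 5), "1..4")
  expect_error(cutTreeK(hc$tree, 0), "1..4")
  # cluster 1 always contains the first sample
  set.seed(2)
  v <- matrix(rnorm(60), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  hc2 <- hierarchicalCluster(v, distance = "euclidean")
  for (k in 2:5) expect_identical(unname(cutTreeK(hc2$tree, k)[1]), 1L)
})

test_that("cutting reproduces the dendrogram partition chain", {
  set.seed(8)
  v <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  hc <- hierarchicalCluster(v, distance = "euclidean")
  # oracle: explicit traversal, successively undoing the last merges
  n <- 8
  memb <- as.list(seq_len(n))  # cluster contents after each merge
  for (i in seq_len(n - 1)) {
    take <- function(x) if (x < 0) -x else memb[[n + x]]
    memb[[n + i]] <- c(take(hc$tree$merge[i, 1]), take(hc$tree$merge[i, 2]))
  }
  for (k in 2:n) {
    lab <- cutTreeK(hc$tree, k)
    # every cluster from a cut at k must be a node of the merge tree
    for (cl in split(seq_len(n), lab)) {
      found <- any(vapply(seq_len(2 * n - 1), function(ix) {
        contents <- if (ix <= n) ix else memb[[ix]]
        setequal(contents, cl)
      }, TRUE))
      expect_true(found)
    }
    expect_identical(length(unique(lab)), as.integer(k))
  }
})

test_that("connectivity index matches hand enumeration and the brute-force oracle", {
  # two well-separated clusters: all neighborhoods co-clustered
  D <- as.matrix(dist(c(0, 0.1, 0.2, 10, 10.1, 10.2)))
  expect_equal(connectivityIndex(D, c(1, 1, 1, 2, 2, 2), L = 2), 0)
  # every sample its own cluster, n=3, L=2: 3 * (1 + 1/2)
  D3 <- as.matrix(dist(c(0, 1, 2)))
  expect_equal(connectivityIndex(D3, 1:3, L = 2), 4.5)
})

test_that("Dunn index matches hand computations", {
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  expect_equal(dunnIndex(D, c(1, 1, 2, 2)), 9)
  # overlapping clusters: diameter exceeds separation
  D2 <- as.matrix(dist(c(0, 5, 1, 6)))
  expect_lt(dunnIndex(D2, c(1, 1, 2, 2)), 1)
  # all-singleton clustering has zero diameters: infinite sentinel
  expect_identical(dunnIndex(D, 1:4), Inf)
  expect_error(dunnIndex(D, rep(1, 4)), "2 clusters")
})

test_that("silhouette approaches 1 for tight distant clusters, 0 for random labels", {
  set.seed(17)
  pts <- c(rnorm(8, 0, 0.001), rnorm(8, 1000, 0.001))
  D <- as.matrix(dist(pts))
  expect_gte(silhouetteIndex(D, rep(1:2, each = 8)), 0.99)
  # random labels on iid points stay near zero on average
  means <- replicate(50, {
    D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    silhouetteIndex(D, sample(1:2, 10, replace = TRUE, prob = c(.5, .5)))
  })
  expect_lt(abs(mean(means, na.rm = TRUE)), 0.1)
})

test_that("silhouette agrees with cluster::silhouette", {
  set.seed(19)
  for (rep in 1:20) {
    rc <- randomClustering(sample(6:12, 1))
    ours <- silhouetteIndex(rc$D, rc$labels)
    ref <- mean(cluster::silhouette(rc$labels, dmatrix = rc$D)[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("three separated blobs select k = 3; singleton k-range is trivial", {
  set.seed(23)
  v <- cbind(matrix(rnorm(30, 0, .2), 3, 10),
             matrix(rnorm(30, 8, .2), 3, 10),
             matrix(rnorm(30, -8, .2), 3, 10))
  dimnames(v) <- list(paste0("g", 1:3), paste0("s", 1:30))
  hc <- hierarchicalCluster(v, distance = "euclidean")
  sol <- selectK(hc$dist, hc$tree, 2:6)
  expect_identical(selectedK(sol), 3L)
  sol2 <- selectK(hc$dist, hc$tree, 2)
  expect_identical(selectedK(sol2), 2L)
  expect_true(all(sol2@votes == 2L))
  expect_error(selectK(hc$dist, hc$tree, integer()), "empty")
})

test_that("synthetic two-subtype data yields k = 2 with unanimous votes and exact labels", {
  sim <- simulateExpression(syntheticConfig(seed = 6))
  res <- runPipeline(sim$matrix)
  expect_identical(selectedK(res$solution), 2L)
  expect_true(all(res$solution@votes == 2L))
  expect_equal(ariIndex(res$labels, sim$truth@subtype[names(res$labels)]), 1)
})
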