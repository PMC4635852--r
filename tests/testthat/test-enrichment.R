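test_that("hypergeometric upper tail matches exact enumeration", {
  # C(2,2)C(2,0)/C(4,2) = 1/6
  expect_equal(hypergeomPvalue(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeomPvalue(100, 10, 5, 0), 1)
  expect_error(hypergeomPvalue(4, 2, 2, 3), "inconsistent")
  expect_error(hypergeomPvalue(4, 5, 2, 1), "inconsistent")
})

test_that("over-representation recovers a fully covered set as top hit", {
  set.seed(51)
  universe <- sprintf("g%04d", 1:1000)
  target <- universe[1:10]
  sets <- c(list(hit = target),
            lapply(1:5, function(i) sample(universe, 25)))
  names(sets) <- c("hit", paste0("rand", 1:5))
  gc <- GeneSetCollection(sets)
  enr <- overrepresentation(target, gc, universe)
  tab <- enrichedSets(enr)
  expect_identical(tab$setId[1], "hit")
  expect_lt(tab$p[1], 1e-15)
  expect_identical(tab$nOverlap[1], 10L)
})

test_that("input disjoint from every set yields an empty result", {
  universe <- sprintf("g%02d", 1:50)
  gc <- GeneSetCollection(list(s1 = universe[1:5], s2 = universe[6:10]))
  enr <- overrepresentation(universe[20:30], gc, universe)
  expect_identical(nrow(enrichedSets(enr)), 0L)
  expect_identical(nrow(enr@allTested), 2L)  # q-values computed over all sets
  expect_error(overrepresentation(character(), gc, universe), "empty input")
  expect_error(overrepresentation("g01", gc, character()), "empty universe")
})

test_that("enrichment p-values ignore gene order and out-of-universe set members", {
  set.seed(53)
  universe <- sprintf("g%02d", 1:60)
  input <- sample(universe, 15)
  gc1 <- GeneSetCollection(list(s = universe[1:12]))
  gc2 <- GeneSetCollection(list(s = c("alien1", rev(universe[1:12]), "alien2")))
  e1 <- overrepresentation(sample(input), gc1, universe, minOverlap = 0,
                           pCutoff = 1.01)
  e2 <- overrepresentation(input, gc2, sample(universe), minOverlap = 0,
                           pCutoff = 1.01)
  expect_equal(enrichedSets(e1)$p, enrichedSets(e2)$p, tolerance = 1e-12)
  expect_identical(enrichedSets(e1)$nSet, enrichedSets(e2)$nSet)
})

test_that("pathway overlap edges follow the 30% smaller-set rule", {
  universe <- c(letters, LETTERS)
  gc <- GeneSetCollection(list(P1 = c("a", "b", "c"), P2 = c("a", "b", "d"),
                               P3 = c("x", "y", "z"), P4 = c("a", "b", "c")))
  enr <- overrepresentation(c("a", "b", "c", "d", "x", "y", "z"),
                            gc, universe, minOverlap = 2, pCutoff = 1.01)
  net <- pathwayOverlapNetwork(enr, gc, edgeMin = 0.30)
  e <- net@edges
  pair <- function(a, b) any((e$setA == a & e$setB == b) |
                             (e$setA == b & e$setB == a))
  frac <- function(a, b) e$overlapFraction[(e$setA == a & e$setB == b) |
                                           (e$setA == b & e$setB == a)]
  expect_true(pair("P1", "P2"))           # {a,b,c} vs {a,b,d}: 2/3
  expect_equal(frac("P1", "P2"), 2 / 3)
  expect_true(pair("P1", "P4"))           # identical: fraction 1
  expect_equal(frac("P1", "P4"), 1)
  expect_false(pair("P1", "P3"))          # disjoint
  expect_true(all(e$overlapFraction >= 0.30 & e$overlapFraction <= 1))
})

test_that("pathway network edge count equals a brute-force all-pairs scan", {
  set.seed(57)
  universe <- sprintf("g%03d", 1:150)
  input <- sample(universe, 50)
  sets <- lapply(1:8, function(i) sample(universe, sample(8:20, 1)))
  names(sets) <- paste0("S", 1:8)
  gc <- GeneSetCollection(sets)
  enr <- overrepresentation(input, gc, universe, minOverlap = 0, pCutoff = 1.01)
  for (basis in c("input_members", "all_members")) {
    net <- pathwayOverlapNetwork(enr, gc, edgeMin = 0.30, overlapBasis = basis)
    ids <- enrichedSets(enr)$setId
    brute <- 0
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      mi <- if (basis == "all_members") sets[[ids[i]]] else
        intersect(sets[[ids[i]]], input)
      mj <- if (basis == "all_members") sets[[ids[j]]] else
        intersect(sets[[ids[j]]], input)
      d <- min(length(mi), length(mj))
      if (d > 0 && length(intersect(mi, mj)) / d >= 0.30) brute <- brute + 1
    }
    expect_identical(nrow(net@edges), as.integer(brute))
  }
})

test_that("module induction applies the per-kind rules", {
  it <- InteractionTable(
    source = c("g1", "g2", "D1", "TF1", "TF2"),
    target = c("g2", "g9", "g1", "g1", "g9"),
    kind = c("ppi", "ppi", "drug_target", "regulatory", "regulatory"),
    role = c(NA, NA, NA, "activator", "repressor"),
    confidence = c(0.95, 0.95, 0.95, 0.95, 0.95))
  mod <- induceModule(c("g1", "g2"), it)
  # ppi needs both endpoints in the input: only g1-g2 survives
  expect_identical(mod@edges$source[mod@edges$kind == "ppi"], "g1")
  # drug and TF attach through their targeted input gene; TF2 targets g9 (out)
  expect_setequal(mod@nodes$id, c("g1", "g2", "D1", "TF1"))
  expect_identical(mod@nodes$type[mod@nodes$id == "D1"], "attached_drug")
  expect_identical(mod@nodes$type[mod@nodes$id == "TF1"], "attached_regulator")
  expect_true(all(mod@nodes$inInput[mod@nodes$id %in% c("g1", "g2")]))
  expect_error(induceModule("g1", it, kind = "telepathy"), "unknown")
  # kind restriction
  ppiOnly <- induceModule(c("g1", "g2"), it, kind = "ppi")
  expect_setequal(ppiOnly@nodes$id, c("g1", "g2"))
})

test_that("low-confidence edges are dropped and restriction is monotone", {
  set.seed(59)
  genes <- sprintf("g%02d", 1:30)
  n <- 120
  src <- sample(c(genes, paste0("TF", 1:3), paste0("D", 1:3)), n, TRUE)
  tgt <- sample(genes, n, TRUE)
  knd <- sample(c("ppi", "regulatory", "drug_target"), n, TRUE)
  ok <- !(knd == "drug_target" & src == tgt)  # keep the table valid
  it <- InteractionTable(src[ok], tgt[ok], knd[ok], role = NA,
                         confidence = runif(sum(ok), 0.3, 1))
  e <- interactionEdges(it)
  input <- sample(genes, 12)
  for (cmin in c(0.5, 0.7, 0.9, 0.95)) {
    mod <- induceModule(input, it, confidenceMin = cmin)
    # oracle: brute-force filter
    keep <- e$confidence >= cmin &
      ((e$kind == "ppi" & e$source %in% input & e$target %in% input) |
       (e$kind != "ppi" & e$target %in% input))
    expect_identical(nrow(mod@edges), as.integer(sum(keep)))
    # no edge invented: every module edge appears in the input table
    merged <- merge(mod@edges, e)
    expect_gte(nrow(merged), nrow(mod@edges))
    # every attached node touches an input gene
    att <- mod@nodes$id[!mod@nodes$inInput]
    for (a in att)
      expect_true(any(mod@edges$source == a & mod@edges$target %in% input))
  }
  # monotone: raising the threshold never adds edges
  n1 <- nrow(induceModule(input, it, confidenceMin = 0.6)@edges)
  n2 <- nrow(induceModule(input, it, confidenceMin = 0.8)@edges)
  expect_gte(n1, n2)
})

test_that("three-way analysis keeps lists independent and tolerates empties", {
  sim <- simulateExpression(syntheticConfig(seed = 61))
  gs <- geneSets(sim$truth)
  gc <- simulateGeneSets(sim$truth)
  part <- new("GenePartition", core = gs$core, uniqueA = gs$unique_a,
              uniqueB = character())
  expect_warning(
    res <- runThreeWay(part, gc, NULL, universe = names(sim$truth@geneClass)),
    "empty gene list")
  expect_null(res$uniqueB$enrichment)
  coreTab <- enrichedSets(res$core$enrichment)
  expect_true("set_core" %in% coreTab$setId)
  expect_false("set_unique_a" %in% coreTab$setId)
  aTab <- enrichedSets(res$uniqueA$enrichment)
  expect_true("set_unique_a" %in% aTab$setId)
  expect_false("set_core" %in% aTab$setId)
})
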