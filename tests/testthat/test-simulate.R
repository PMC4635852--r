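test_that("a fixed seed reproduces the dataset bit for bit", {
  a <- simulateExpression(syntheticConfig(seed = 1))
  b <- simulateExpression(syntheticConfig(seed = 1))
  expect_identical(exprValues(a$matrix), exprValues(b$matrix))
  expect_identical(a$truth@geneClass, b$truth@geneClass)
  c2 <- simulateExpression(syntheticConfig(seed = 2))
  expect_false(identical(exprValues(a$matrix), exprValues(c2$matrix)))
  # generator calls do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateExpression(syntheticConfig(seed = 3)))
  expect_identical(rnorm(1), before)
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(fracCore = 0.6, fracUniqueA = 0.3,
                               fracUniqueB = 0.2), "sum below 1")
  expect_error(syntheticConfig(nGenes = 0), "positive")
  expect_error(syntheticConfig(noiseSd = 0), "noiseSd")
})

test_that("planted structure matches the configuration", {
  cfg <- syntheticConfig(seed = 5)
  sim <- simulateExpression(cfg)
  truth <- sim$truth
  cl <- table(truth@geneClass)
  expect_identical(as.integer(cl["core"]), 100L)
  expect_identical(as.integer(cl["unique_a"]), 60L)
  expect_identical(as.integer(cl["unique_b"]), 60L)
  expect_identical(length(truth@outliers), 3L)
  g <- sampleGroups(sim$matrix)
  expect_identical(sum(g == "TCMR"), 31L)  # 14 + 14 + 3 outliers
  expect_identical(sum(g == "Neph"), 8L)
  # planted shifts land where intended: core shifted in both subtypes
  v <- exprValues(sim$matrix)
  gs <- geneSets(truth)
  st <- truth@subtype
  inA <- setdiff(names(st)[st == "A"], truth@outliers)
  inB <- setdiff(names(st)[st == "B"], truth@outliers)
  ctrl <- names(g)[g == "Neph"]
  coreShiftA <- mean(v[gs$core, inA]) - mean(v[gs$core, ctrl])
  coreShiftB <- mean(v[gs$core, inB]) - mean(v[gs$core, ctrl])
  uaShiftA <- mean(v[gs$unique_a, inA]) - mean(v[gs$unique_a, ctrl])
  uaShiftB <- mean(v[gs$unique_a, inB]) - mean(v[gs$unique_a, ctrl])
  expect_equal(coreShiftA, 2, tolerance = 0.15)
  expect_equal(coreShiftB, 2, tolerance = 0.15)
  expect_equal(uaShiftA, 2, tolerance = 0.15)
  expect_equal(uaShiftB, 0, tolerance = 0.15)
})

test_that("the default filter retains the planted differential genes", {
  for (s in 1:3) {
    sim <- simulateExpression(syntheticConfig(seed = 300 + s))
    kept <- geneIDs(filterGenes(sim$matrix)$matrix)
    planted <- names(sim$truth@geneClass)[sim$truth@geneClass != "null"]
    expect_gte(length(intersect(planted, kept)) / length(planted), 0.99)
  }
})

test_that("zero effect size leaves subtypes unrecoverable", {
  aris <- vapply(1:8, function(s) {
    sim <- simulateExpression(syntheticConfig(effectSize = 0, seed = 400 + s))
    res <- runPipeline(sim$matrix)
    lab <- res$labels
    ariIndex(lab, sim$truth@subtype[names(lab)])
  }, 0)
  expect_lt(abs(mean(aris)), 0.15)
})

test_that("raising the effect size weakly improves recovery", {
  recov <- vapply(c(0, 1, 2, 4), function(es) {
    mean(vapply(1:3, function(s) {
      sim <- simulateExpression(syntheticConfig(effectSize = es, seed = 500 + s))
      res <- runPipeline(sim$matrix)
      ariIndex(res$labels, sim$truth@subtype[names(res$labels)])
    }, 0))
  }, 0)
  expect_true(all(diff(recov) >= -0.05))
  expect_gt(recov[4], 0.9)
})

test_that("generated gene sets are class-anchored with null-only decoys", {
  sim <- simulateExpression(syntheticConfig(seed = 9))
  gc <- simulateGeneSets(sim$truth, nDecoySets = 0)
  expect_identical(length(setIDs(gc)), 3L)
  gc2 <- simulateGeneSets(sim$truth, nDecoySets = 7, setSize = 20)
  expect_identical(length(setIDs(gc2)), 10L)
  gs <- geneSets(sim$truth)
  sets <- geneSets(gc2)
  for (cl in c("core", "unique_a", "unique_b")) {
    s <- sets[[paste0("set_", cl)]]
    expect_identical(length(s), 20L)
    expect_gte(length(intersect(s, gs[[cl]])) / length(s), 0.8)
    # filler never comes from the other planted classes
    other <- setdiff(unlist(gs[setdiff(names(gs), c(cl, "null"))]), gs[[cl]])
    expect_length(intersect(setdiff(s, gs[[cl]]), other), 0)
  }
  for (d in grep("^decoy", names(sets), value = TRUE))
    expect_true(all(sets[[d]] %in% gs$null))
  # deterministic under the derived seed
  expect_identical(geneSets(simulateGeneSets(sim$truth)),
                   geneSets(simulateGeneSets(sim$truth)))
})

test_that("generated interactions satisfy the table invariants across seeds", {
  for (s in 1:25) {
    sim <- simulateExpression(syntheticConfig(nGenes = 300, seed = 600 + s))
    it <- simulateInteractions(sim$truth, density = 0.05)
    e <- interactionEdges(it)
    expect_true(all(e$kind %in% c("ppi", "regulatory", "drug_target")))
    expect_true(all(e$confidence >= 0.5 & e$confidence <= 1))
    expect_false(any(e$kind == "drug_target" & e$source == e$target))
    expect_true(validObject(it))
  }
})

test_that("module induction recovers the class TF and drug anchors", {
  sim <- simulateExpression(syntheticConfig(seed = 11))
  it <- simulateInteractions(sim$truth)
  gs <- geneSets(sim$truth)
  modA <- induceModule(gs$unique_a, it, kind = c("regulatory", "drug_target"))
  expect_true("TF_A" %in% modA@nodes$id)
  expect_true("DRUG_A" %in% modA@nodes$id)
  expect_false("TF_B" %in% modA@nodes$id)
  expect_false("DRUG_CORE" %in% modA@nodes$id)
  expect_gte(sum(modA@edges$source == "TF_A"), 5)
  expect_gte(sum(modA@edges$source == "DRUG_A"), 3)
  expect_error(simulateInteractions(sim$truth, density = 0), "density")
})

test_that("a synthetic dataset round-trips through the on-disk formats", {
  dir <- file.path(tempdir(), "simds")
  writeSyntheticDataset(syntheticConfig(nGenes = 600, seed = 13), dir)
  em <- readExpressionTSV(file.path(dir, "expr.tsv"),
                          file.path(dir, "groups.tsv"))
  sim <- simulateExpression(syntheticConfig(nGenes = 600, seed = 13))
  expect_equal(exprValues(em), exprValues(sim$matrix), tolerance = 1e-4)
  expect_identical(sampleGroups(em), sampleGroups(sim$matrix))
  gc <- readGMT(file.path(dir, "sets.gmt"))
  expect_identical(geneSets(gc), geneSets(simulateGeneSets(sim$truth)))
  ppi <- readInteractions(file.path(dir, "ppi.tsv"), "ppi")
  expect_gt(nrow(interactionEdges(ppi)), 0)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(unlist(truth$outliers), sim$truth@outliers)
})
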