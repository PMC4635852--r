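#' Build a synthetic-data configuration
#'
#' Defaults mirror the cohort the pipeline is designed for: 31 case
#' biopsies (14 per planted subtype plus 3 outliers) against 8 controls,
#' with core/unique-A/unique-B planted gene classes at 5%/3%/3% of a
#' 2000-gene background, a 2-sd mean shift, and 6-sd outlier shifts on a
#' random half of the genes.
#'
#' @param nGenes,nPerSubtype,nControl,nOutliers cohort dimensions.
#' @param fracCore,fracUniqueA,fracUniqueB planted gene-class fractions.
#' @param effectSize,outlierShift,noiseSd log2-scale effect parameters
#'   (shifts are in units of `noiseSd`).
#' @param baselineRange baseline mean range for background genes.
#' @param seed RNG seed; fixed seed makes every generator output
#'   bit-identical.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nGenes = 2000, nPerSubtype = 14, nControl = 8,
                            nOutliers = 3, fracCore = 0.05,
                            fracUniqueA = 0.03, fracUniqueB = 0.03,
                            effectSize = 2.0, outlierShift = 6.0,
                            noiseSd = 1.0, baselineRange = c(4, 12),
                            seed = 1L) {
  new("SyntheticConfig", nGenes = as.integer(nGenes),
      nPerSubtype = as.integer(nPerSubtype), nControl = as.integer(nControl),
      nOutliers = as.integer(nOutliers), fracCore = fracCore,
      fracUniqueA = fracUniqueA, fracUniqueB = fracUniqueB,
      effectSize = effectSize, outlierShift = outlierShift,
      noiseSd = noiseSd, baselineRange = as.numeric(baselineRange),
      seed = as.integer(seed))
}

withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic expression dataset with planted ground truth
#'
#' Genes are split into `core` (shifted by `effectSize * noiseSd` in both
#' subtypes versus control), `unique_a` (shifted only in subtype A),
#' `unique_b` (only in B) and `null`. Case samples carry group label
#' `"TCMR"`, controls `"Neph"`. Planted outliers are extra case samples
#' receiving an additional `outlierShift * noiseSd` on a random half of the
#' genes. Background gene baselines are uniform on `baselineRange`; planted
#' gene baselines are drawn from the lower-middle of that range
#' (`[4.5, 6]` at defaults) so the default expression/CV filter retains
#' them.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `matrix` (an [ExpressionMatrix-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
simulateExpression <- function(config = syntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  withSeed(config@seed, {
    nG <- config@nGenes
    genes <- sprintf("g%04d", seq_len(nG))
    nCore <- round(config@fracCore * nG)
    nUa <- round(config@fracUniqueA * nG)
    nUb <- round(config@fracUniqueB * nG)
    if (nCore + nUa + nUb >= nG) stop("infeasible planted gene fractions")
    cls <- rep("null", nG)
    planted <- sample.int(nG, nCore + nUa + nUb)
    cls[planted[seq_len(nCore)]] <- "core"
    cls[planted[nCore + seq_len(nUa)]] <- "unique_a"
    cls[planted[nCore + nUa + seq_len(nUb)]] <- "unique_b"
    names(cls) <- genes

    sidA <- sprintf("A%02d", seq_len(config@nPerSubtype))
    sidB <- sprintf("B%02d", seq_len(config@nPerSubtype))
    sidO <- if (config@nOutliers > 0) sprintf("O%d", seq_len(config@nOutliers))
            else character()
    sidN <- sprintf("N%02d", seq_len(config@nControl))
    subtype <- c(stats::setNames(rep("A", length(sidA)), sidA),
                 stats::setNames(rep("B", length(sidB)), sidB),
                 stats::setNames(rep(c("A", "B"), length.out = length(sidO)),
                                 sidO))
    samples <- c(sidA, sidB, sidO, sidN)
    groups <- stats::setNames(
      c(rep("TCMR", length(subtype)), rep("Neph", length(sidN))), samples)

    baseline <- stats::runif(nG, config@baselineRange[1], config@baselineRange[2])
    lo <- max(config@baselineRange[1] + 0.5, config@baselineRange[1])
    hi <- min(lo + 1.5, config@baselineRange[2])
    baseline[cls != "null"] <- stats::runif(sum(cls != "null"), lo, hi)

    v <- matrix(stats::rnorm(nG * length(samples), sd = config@noiseSd),
                nG, length(samples), dimnames = list(genes, samples)) + baseline
    shift <- config@effectSize * config@noiseSd
    inA <- samples %in% names(subtype)[subtype == "A"]
    inB <- samples %in% names(subtype)[subtype == "B"]
    v[cls == "core", inA | inB] <- v[cls == "core", inA | inB] + shift
    v[cls == "unique_a", inA] <- v[cls == "unique_a", inA] + shift
    v[cls == "unique_b", inB] <- v[cls == "unique_b", inB] + shift
    for (o in sidO) {
      hit <- sample.int(nG, floor(nG / 2))
      v[hit, o] <- v[hit, o] + config@outlierShift * config@noiseSd
    }
    truth <- new("GroundTruth", subtype = subtype, outliers = sidO,
                 geneClass = cls, config = config)
    list(matrix = ExpressionMatrix(v, groups), truth = truth)
  })
}

#' Generate gene-set collections matched to the planted classes
#'
#' One set per planted class, drawn at least 80% from that class (the rest
#' from null genes), plus `nDecoySets` decoy sets drawn uniformly from the
#' null genes.
#'
#' @param truth a [GroundTruth-class].
#' @param nDecoySets number of decoy sets (default 20).
#' @param setSize members per set (default 20).
#' @param seed RNG seed (default: generator seed + 1).
#' @return a [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(truth, nDecoySets = 20, setSize = 20,
                             seed = truth@config@seed + 1L) {
  byClass <- split(names(truth@geneClass), truth@geneClass)
  nullGenes <- byClass$null
  nFromClass <- ceiling(0.8 * setSize)
  withSeed(seed, {
    sets <- list()
    desc <- character()
    for (cl in c("core", "unique_a", "unique_b")) {
      pool <- byClass[[cl]]
      if (is.null(pool) || length(pool) < nFromClass)
        stop("class '", cl, "' too small for setSize ", setSize)
      sets[[paste0("set_", cl)]] <-
        c(sample(pool, nFromClass),
          sample(nullGenes, setSize - nFromClass))
      desc <- c(desc, paste("planted", cl, "set"))
    }
    if (nDecoySets > 0) for (i in seq_len(nDecoySets)) {
      sets[[sprintf("decoy%02d", i)]] <- sample(nullGenes, setSize)
      desc <- c(desc, "decoy set of null genes")
    }
    GeneSetCollection(sets, desc)
  })
}

#' Generate an interaction table matched to the planted classes
#'
#' Random PPI edges enriched within each planted class, one synthetic
#' transcription factor per class regulating at least 5 class genes, and
#' one synthetic drug per class targeting at least 3 class genes. Anchor
#' (TF/drug) edges draw confidence in `[0.9, 1]` so default high-confidence
#' induction recovers them; background edges draw from `[0.5, 1]`.
#'
#' @param truth a [GroundTruth-class].
#' @param density within-class PPI edge density in `(0, 1]` (default 0.05);
#'   the `density -> 0` limit gives an empty table.
#' @param seed RNG seed (default: generator seed + 2).
#' @return an [InteractionTable-class].
#' @export
simulateInteractions <- function(truth, density = 0.05,
                                 seed = truth@config@seed + 2L) {
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  byClass <- split(names(truth@geneClass), truth@geneClass)
  allGenes <- names(truth@geneClass)
  withSeed(seed, {
    src <- tgt <- knd <- rol <- character(); cnf <- numeric()
    addEdges <- function(s, t, k, r, cf) {
      src <<- c(src, s); tgt <<- c(tgt, t); knd <<- c(knd, rep(k, length(s)))
      rol <<- c(rol, r); cnf <<- c(cnf, cf)
    }
    tfTag <- c(core = "TF_CORE", unique_a = "TF_A", unique_b = "TF_B")
    drugTag <- c(core = "DRUG_CORE", unique_a = "DRUG_A", unique_b = "DRUG_B")
    for (cl in c("core", "unique_a", "unique_b")) {
      pool <- byClass[[cl]]
      nPairs <- round(density * choose(length(pool), 2))
      if (nPairs > 0) {
        i <- sample.int(length(pool), nPairs, replace = TRUE)
        j <- sample.int(length(pool), nPairs, replace = TRUE)
        ok <- i != j
        addEdges(pool[i[ok]], pool[j[ok]], "ppi",
                 rep(NA_character_, sum(ok)), stats::runif(sum(ok), 0.5, 1))
      }
      nReg <- max(5L, round(density * length(pool)))
      regT <- sample(pool, min(nReg, length(pool)))
      addEdges(rep(tfTag[[cl]], length(regT)), regT, "regulatory",
               sample(c("activator", "repressor"), length(regT), TRUE),
               stats::runif(length(regT), 0.9, 1))
      nDrug <- max(3L, round(density * length(pool) / 2))
      drgT <- sample(pool, min(nDrug, length(pool)))
      addEdges(rep(drugTag[[cl]], length(drgT)), drgT, "drug_target",
               rep(NA_character_, length(drgT)),
               stats::runif(length(drgT), 0.9, 1))
    }
    # sparse background over all genes
    nBg <- round(density * length(allGenes) / 4)
    if (nBg > 0) {
      i <- sample.int(length(allGenes), nBg, replace = TRUE)
      j <- sample.int(length(allGenes), nBg, replace = TRUE)
      ok <- i != j
      addEdges(allGenes[i[ok]], allGenes[j[ok]], "ppi",
               rep(NA_character_, sum(ok)), stats::runif(sum(ok), 0.5, 1))
      bgT <- sample(byClass$null, min(nBg, length(byClass$null)))
      addEdges(rep("TF_NULL", length(bgT)), bgT, "regulatory",
               sample(c("activator", "repressor", "product"),
                      length(bgT), TRUE),
               stats::runif(length(bgT), 0.5, 1))
    }
    InteractionTable(src, tgt, knd, rol, cnf)
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Writes `expr.tsv`, `groups.tsv`, `truth.json`, `sets.gmt`, and one edge
#' list per interaction kind (`ppi.tsv`, `regulatory.tsv`, `drugs.tsv`).
#'
#' @param config a [SyntheticConfig-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSyntheticDataset <- function(config = syntheticConfig(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateExpression(config)
  writeExpressionTSV(sim$matrix, file.path(dir, "expr.tsv"),
                     groupPath = file.path(dir, "groups.tsv"))
  writeGMT(simulateGeneSets(sim$truth), file.path(dir, "sets.gmt"))
  inter <- simulateInteractions(sim$truth)
  e <- interactionEdges(inter)
  for (spec in list(c("ppi", "ppi.tsv"), c("regulatory", "regulatory.tsv"),
                    c("drug_target", "drugs.tsv"))) {
    sub <- new("InteractionTable", edges = e[e$kind == spec[1], , drop = FALSE])
    writeInteractions(sub, file.path(dir, spec[2]))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(subtype = as.list(truth@subtype), outliers = truth@outliers,
         geneClass = as.list(truth@geneClass), seed = config@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
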