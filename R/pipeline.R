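#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter with its default. Partial
#' overrides are merged with [runPipeline()]'s `config` argument; unknown
#' keys are rejected before any stage runs.
#'
#' @return nested named list.
#' @export
pipelineDefaults <- function() {
  list(
    groups = list(case = "TCMR", control = "Neph"),
    filter = list(scaledMin = 0.12, cvMin = 0.12),
    outliers = list(dim = 2, centerMode = "medoid", zThreshold = 2),
    cluster = list(distance = "one_minus_pearson", linkage = "average",
                   kMin = 2, kMax = 6, L = 10),
    de = list(alpha = 0.05, gate = "q", varianceMode = "pooled"),
    enrich = list(minOverlap = 2, pCutoff = 0.01, edgeMin = 0.30,
                  overlapBasis = "input_members", confidenceMin = 0.9))
}

mergeConfig <- function(defaults, override, path = character()) {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown config key: ",
         paste(c(path, unknown[1]), collapse = "."))
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], override[[nm]],
                                    c(path, nm))
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full subtype-discovery pipeline
#'
#' Chains every stage: gene filtering on original-scale statistics,
#' per-gene z-scoring, MDS outlier flagging among the case samples,
#' outlier removal (followed by re-z-scoring the retained samples),
#' hierarchical clustering with validity-index k selection, differential
#' expression (subtype vs subtype and each subtype vs control),
#' core/unique gene partitioning, and per-list over-representation plus
#' pathway-overlap and induced interaction networks. All stage outputs and
#' a JSON run manifest (effective config, output checksums) are written to
#' `outDir`.
#'
#' @param x an [ExpressionMatrix-class] (or path to an expression TSV).
#' @param groupPath optional group-map TSV when `x` is a path.
#' @param collection optional [GeneSetCollection-class] (or GMT path) for
#'   enrichment; skipped when `NULL`.
#' @param interactions optional [InteractionTable-class] for induced
#'   modules.
#' @param config partial override of [pipelineDefaults()].
#' @param outDir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return (invisibly) list with elements `filter`, `embedding`,
#'   `solution`, `labels`, `de` (named list of [DEResult-class]),
#'   `partition`, `networks`, `config`, `outDir`.
#' @export
runPipeline <- function(x, groupPath = NULL, collection = NULL,
                        interactions = NULL, config = list(),
                        outDir = NULL) {
  cfg <- mergeConfig(pipelineDefaults(), config)
  if (is.character(x)) x <- readExpressionTSV(x, groupPath)
  if (is.character(collection)) collection <- readGMT(collection)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  groups <- sampleGroups(x)
  caseIds <- names(groups)[groups == cfg$groups$case]
  ctrlIds <- names(groups)[groups == cfg$groups$control]
  if (length(caseIds) < 4) stop("need at least 4 case samples")

  filt <- stage("filter", filterGenes(x, cfg$filter$scaledMin, cfg$filter$cvMin))
  zAll <- stage("normalize", zscoreNormalize(filt$matrix))

  emb <- stage("outliers", detectOutlierSamples(
    exprValues(zAll)[, caseIds, drop = FALSE], k = cfg$outliers$dim,
    centerMode = cfg$outliers$centerMode,
    zThreshold = cfg$outliers$zThreshold))
  keepCase <- setdiff(caseIds, outlierSamples(emb))

  retained <- c(keepCase, ctrlIds)
  zRet <- stage("renormalize", zscoreNormalize(
    ExpressionMatrix(exprValues(filt$matrix)[, retained, drop = FALSE],
                     groups[retained])))

  hc <- stage("cluster", hierarchicalCluster(
    exprValues(zRet)[, keepCase, drop = FALSE],
    distance = cfg$cluster$distance, linkage = cfg$cluster$linkage))
  sol <- stage("selectK", selectK(hc$dist, hc$tree,
                                  kRange = cfg$cluster$kMin:cfg$cluster$kMax,
                                  L = cfg$cluster$L))
  labels <- clusterLabels(sol, selectedK(sol))

  subLab <- groups[retained]
  subLab[names(labels)] <- paste0("S", labels)
  de <- stage("de", {
    out <- list()
    nOf <- function(g) sum(subLab == g)
    # contrasts are only run when both groups have >= 2 samples (a singleton
    # cluster cannot support a t test)
    if (selectedK(sol) >= 2 && nOf("S1") >= 2 && nOf("S2") >= 2)
      out$S1_vs_S2 <- differentialGenes(zRet, subLab, "S1", "S2",
        alpha = cfg$de$alpha, gate = cfg$de$gate,
        varianceMode = cfg$de$varianceMode)
    if (length(ctrlIds) >= 2) {
      for (s in paste0("S", seq_len(min(selectedK(sol), 2))))
        if (nOf(s) >= 2)
          out[[paste0(s, "_vs_control")]] <- differentialGenes(
            zRet, subLab, s, cfg$groups$control, alpha = cfg$de$alpha,
            gate = cfg$de$gate, varianceMode = cfg$de$varianceMode)
    }
    out
  })

  partition <- NULL
  networks <- NULL
  if (!is.null(de$S1_vs_control) && !is.null(de$S2_vs_control)) {
    partition <- stage("partition",
                       partitionGenes(de$S1_vs_control, de$S2_vs_control))
    if (!is.null(collection))
      networks <- stage("networks", suppressWarnings(runThreeWay(
        partition, collection, interactions, universe = geneIDs(filt$matrix),
        minOverlap = cfg$enrich$minOverlap, pCutoff = cfg$enrich$pCutoff,
        edgeMin = cfg$enrich$edgeMin, overlapBasis = cfg$enrich$overlapBasis,
        confidenceMin = cfg$enrich$confidenceMin)))
  }

  if (!is.null(outDir))
    stage("write", writePipelineOutputs(outDir, cfg, filt, emb, sol, labels,
                                        de, partition, networks))
  invisible(list(filter = filt, embedding = emb, solution = sol,
                 labels = labels, de = de, partition = partition,
                 networks = networks, config = cfg, outDir = outDir))
}

writePipelineOutputs <- function(outDir, cfg, filt, emb, sol, labels, de,
                                 partition, networks) {
  writeExpressionTSV(filt$matrix, file.path(outDir, "filtered.tsv"))
  rep <- filt$report
  num <- vapply(rep, is.numeric, TRUE)
  rep[num] <- lapply(rep[num], signif, 6)
  utils::write.table(rep, file.path(outDir, "filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeEmbeddingTSV(emb, file.path(outDir, "embedding.tsv"))
  utils::write.table(
    data.frame(sample = names(labels), cluster = unname(labels)),
    file.path(outDir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tr <- sol@tree
  jsonlite::write_json(
    list(merge = apply(tr$merge, 1, as.list),
         height = signif(tr$height, 6), labels = tr$labels,
         indices = sol@indices, votes = as.list(sol@votes),
         selected_k = sol@selectedK),
    file.path(outDir, "solution.json"), auto_unbox = TRUE, digits = 6)
  for (nm in names(de))
    writeDETSV(de[[nm]], file.path(outDir, paste0("de_", nm, ".tsv")))
  if (!is.null(partition))
    jsonlite::write_json(
      list(core = partition@core, unique_a = partition@uniqueA,
           unique_b = partition@uniqueB),
      file.path(outDir, "partition.json"))
  if (!is.null(networks)) for (nm in names(networks)) {
    res <- networks[[nm]]
    if (is.null(res$enrichment)) next
    tab <- res$enrichment@table
    numc <- vapply(tab, is.numeric, TRUE)
    tab[numc] <- lapply(tab[numc], signif, 6)
    utils::write.table(tab, file.path(outDir, paste0("enrich_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res$pathwayNetwork@nodes))
      writeModuleGraphML(res$pathwayNetwork,
                         file.path(outDir, paste0("pathways_", nm, ".graphml")))
    for (k in names(res$modules)) {
      mod <- res$modules[[k]]
      if (nrow(mod@nodes))
        writeModuleGraphML(mod,
          file.path(outDir, sprintf("module_%s_%s.graphml", nm, k)))
      if (nrow(mod@edges))
        writeSIF(mod@edges,
                 file.path(outDir, sprintf("module_%s_%s.sif", nm, k)))
    }
  }
  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  sums <- tools::md5sum(file.path(outDir, files))
  jsonlite::write_json(
    list(config = cfg, outputs = as.list(stats::setNames(unname(sums), files))),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  invisible(outDir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file mirroring [pipelineDefaults()] and validates it
#' (unknown keys rejected).
#'
#' @param path YAML path.
#' @return the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  mergeConfig(pipelineDefaults(), yaml::read_yaml(path))
}
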