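#' Accessors for pipeline objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access: `exprValues()` returns the genes-by-samples matrix,
#' `sampleGroups()` the named group vector, `geneIDs()`/`sampleIDs()` the
#' dimension names, `geneSets()`/`setIDs()` the gene-set members and IDs,
#' `interactionEdges()` the typed edge table, `outlierSamples()` the flagged
#' sample IDs, `clusterLabels()` the per-k labels, `selectedK()` the chosen
#' cluster count, `significantGenes()` the genes passing the DE gate, and
#' `enrichedSets()` the reported enrichment table.
#'
#' @param x an object of the documented class.
#' @param k cluster count (for `clusterLabels`).
#' @return see the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setIDs", function(x) standardGeneric("setIDs"))
#' @rdname accessors
#' @export
setGeneric("interactionEdges", function(x) standardGeneric("interactionEdges"))
#' @rdname accessors
#' @export
setGeneric("outlierSamples", function(x) standardGeneric("outlierSamples"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, k) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))
#' @rdname accessors
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))
#' @rdname accessors
#' @export
setGeneric("enrichedSets", function(x) standardGeneric("enrichedSets"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionMatrix", function(x) {
  g <- SummarizedExperiment::colData(x)$group
  names(g) <- colnames(x)
  g
})

#' @rdname accessors
#' @export
setMethod("geneIDs", "ExpressionMatrix", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("sampleIDs", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) {
  m <- x@members
  names(m) <- x@setIds
  m
})
#' @rdname accessors
#' @export
setMethod("setIDs", "GeneSetCollection", function(x) x@setIds)

#' @rdname accessors
#' @export
setMethod("interactionEdges", "InteractionTable", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("outlierSamples", "EmbeddingReport", function(x) x@outliers)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterSolution", function(x, k) {
  if (missing(k)) k <- x@selectedK
  kc <- as.character(k)
  if (!kc %in% colnames(x@labelsByK))
    stop("no labels stored for k=", k)
  lab <- x@labelsByK[, kc]
  names(lab) <- rownames(x@labelsByK)
  lab
})

#' @rdname accessors
#' @export
setMethod("selectedK", "ClusterSolution", function(x) x@selectedK)

#' @rdname accessors
#' @export
setMethod("significantGenes", "DEResult", function(x) x@significant)

#' @rdname accessors
#' @export
setMethod("enrichedSets", "EnrichmentResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("geneSets", "GroundTruth", function(x) {
  split(names(x@geneClass), x@geneClass)
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@setIds), "sets; sizes",
      if (length(object@setIds)) paste0(min(lengths(object@members)), "-",
                                        max(lengths(object@members))) else "-", "\n")
})

setMethod("show", "InteractionTable", function(object) {
  e <- object@edges
  cat("InteractionTable with", nrow(e), "edges\n")
  if (nrow(e)) print(table(e$kind))
})

setMethod("show", "EmbeddingReport", function(object) {
  cat(sprintf("EmbeddingReport: %d samples embedded in %d dimensions (%s center)\n",
              nrow(object@coordinates), ncol(object@coordinates), object@centerMode))
  cat(sprintf("  outliers (z > %g): %s\n", object@zThreshold,
              if (length(object@outliers)) paste(object@outliers, collapse = ", ") else "none"))
  if (object@degenerate) cat("  note: degenerate spread (all distances equal)\n")
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution over %d samples; k evaluated: %s\n",
              nrow(object@labelsByK), paste(colnames(object@labelsByK), collapse = ", ")))
  cat(sprintf("  selected k = %d (votes: %s)\n", object@selectedK,
              paste(sprintf("%s->%d", names(object@votes), object@votes), collapse = ", ")))
})

setMethod("show", "DEResult", function(object) {
  cat(sprintf("DEResult: %s vs %s, %d genes tested, %d significant (%s < %g)\n",
              object@groups[1], object@groups[2], nrow(object@table),
              length(object@significant), object@gate, object@alpha))
})

setMethod("show", "GenePartition", function(object) {
  cat(sprintf("GenePartition: core %d, unique-A %d, unique-B %d genes\n",
              length(object@core), length(object@uniqueA), length(object@uniqueB)))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d/%d sets reported (overlap >= %d, p < %g)\n",
              nrow(object@table), nrow(object@allTested),
              object@parameters$minOverlap, object@parameters$pCutoff))
  if (nrow(object@table))
    print(utils::head(object@table[, c("setId", "nOverlap", "p", "q")], 5))
})

setMethod("show", "InducedModule", function(object) {
  cat(sprintf("InducedModule (%s, confidence >= %g): %d nodes, %d edges\n",
              paste(object@kinds, collapse = "+"), object@confidenceMin,
              nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "GroundTruth", function(object) {
  cl <- table(object@geneClass)
  cat("GroundTruth:", length(object@subtype), "case samples,",
      length(object@outliers), "planted outliers\n  gene classes:",
      paste(sprintf("%s=%d", names(cl), cl), collapse = ", "), "\n")
})
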