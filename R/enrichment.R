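#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `nOverlap` members of a gene set in a
#' drawn input list: `P[X >= nOverlap]` with
#' `X ~ Hypergeometric(nUniverse, nSet, nInput)`.
#'
#' @param nUniverse universe size.
#' @param nSet gene-set size within the universe.
#' @param nInput input-list size within the universe.
#' @param nOverlap observed overlap.
#' @return p-value in `(0, 1]`; `nOverlap = 0` gives exactly 1.
#' @export
hypergeomPvalue <- function(nUniverse, nSet, nInput, nOverlap) {
  if (nOverlap < 0 || nSet < 0 || nInput < 0 || nUniverse < 0 ||
      nSet > nUniverse || nInput > nUniverse ||
      nOverlap > min(nSet, nInput))
    stop("inconsistent hypergeometric counts")
  stats::phyper(nOverlap - 1, nSet, nUniverse - nSet, nInput,
                lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests every set in the collection against the input gene list. Set
#' members are first intersected with the universe; genes of the input list
#' outside the universe are dropped. BH q-values are computed over all
#' tested sets; the reported table then keeps sets with
#' `nOverlap >= minOverlap` and `p < pCutoff`, sorted by p.
#'
#' @param genes input gene IDs.
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector of genes that could have been selected
#'   (e.g. the filtered gene list).
#' @param minOverlap minimum input genes in a reported set (default 2).
#' @param pCutoff reporting p-value cutoff (default 0.01).
#' @return an [EnrichmentResult-class].
#' @export
overrepresentation <- function(genes, collection, universe, minOverlap = 2,
                               pCutoff = 0.01) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  input <- intersect(unique(as.character(genes)), universe)
  if (!length(input)) stop("empty input gene list (after universe restriction)")
  sets <- geneSets(collection)
  rows <- lapply(seq_along(sets), function(i) {
    mem <- intersect(sets[[i]], universe)
    ov <- intersect(mem, input)
    data.frame(setId = names(sets)[i],
               description = collection@descriptions[i],
               nUniverse = length(universe), nSet = length(mem),
               nInput = length(input), nOverlap = length(ov),
               p = if (length(mem))
                 hypergeomPvalue(length(universe), length(mem),
                                 length(input), length(ov)) else 1,
               overlapGenes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  all$q <- bhFDR(all$p)
  keep <- all[all$nOverlap >= minOverlap & all$p < pCutoff, , drop = FALSE]
  keep <- keep[order(keep$p, keep$setId), , drop = FALSE]
  rownames(keep) <- NULL
  new("EnrichmentResult", table = keep, allTested = all,
      parameters = list(nUniverse = length(universe),
                        minOverlap = minOverlap, pCutoff = pCutoff))
}

#' Pathway-overlap network over enriched sets
#'
#' Connects two enriched sets when they share at least `edgeMin` (default
#' 30%) of their genes, with the fraction computed as
#' `|shared| / min(|genes_i|, |genes_j|)`. The basis is either the input
#' genes falling in each set (`"input_members"`, default — how overlap
#' graphs are drawn from a user's gene list) or the full set memberships
#' restricted to the universe (`"all_members"`).
#'
#' @param enrichment an [EnrichmentResult-class].
#' @param collection the [GeneSetCollection-class] the enrichment used.
#' @param edgeMin minimum overlap fraction for an edge (default 0.30).
#' @param overlapBasis `"input_members"` or `"all_members"`.
#' @return a [PathwayNetwork-class].
#' @export
pathwayOverlapNetwork <- function(enrichment, collection, edgeMin = 0.30,
                                  overlapBasis = c("input_members",
                                                   "all_members")) {
  overlapBasis <- match.arg(overlapBasis)
  tab <- enrichment@table
  nodes <- tab[, c("setId", "p", "q", "nOverlap")]
  rownames(nodes) <- NULL
  members <- if (overlapBasis == "input_members") {
    stats::setNames(strsplit(tab$overlapGenes, ";", fixed = TRUE), tab$setId)
  } else {
    allSets <- geneSets(collection)
    lapply(stats::setNames(tab$setId, tab$setId), function(s) allSets[[s]])
  }
  edges <- data.frame(setA = character(), setB = character(),
                      overlapFraction = numeric())
  n <- nrow(tab)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      mi <- members[[tab$setId[i]]]; mj <- members[[tab$setId[j]]]
      denom <- min(length(mi), length(mj))
      frac <- if (denom > 0) length(intersect(mi, mj)) / denom else 0
      if (frac >= edgeMin)
        edges <- rbind(edges, data.frame(setA = tab$setId[i],
                                         setB = tab$setId[j],
                                         overlapFraction = frac))
    }
  }
  rownames(edges) <- NULL
  new("PathwayNetwork", nodes = nodes, edges = edges, edgeMin = edgeMin,
      overlapBasis = overlapBasis)
}

#' Induce an interaction module around an input gene list
#'
#' Applies the induction rule per interaction kind after dropping edges
#' below the high-confidence threshold: `ppi` edges are kept only when both
#' endpoints are input genes; `regulatory` and `drug_target` edges are kept
#' when the target is an input gene, attaching the non-input regulator or
#' drug as a typed satellite node. No intermediate connector nodes are
#' added.
#'
#' @param genes input gene IDs.
#' @param interactions an [InteractionTable-class].
#' @param kind interaction kinds to include (subset of
#'   `c("ppi", "regulatory", "drug_target")`; default all present).
#' @param confidenceMin minimum edge confidence (default 0.9).
#' @return an [InducedModule-class].
#' @export
induceModule <- function(genes, interactions, kind = NULL,
                         confidenceMin = 0.9) {
  e <- interactionEdges(interactions)
  if (is.null(kind)) kind <- unique(e$kind)
  bad <- setdiff(kind, .INTERACTION_KINDS)
  if (length(bad)) stop("unknown interaction kind: ", paste(bad, collapse = ", "))
  genes <- unique(as.character(genes))
  e <- e[e$kind %in% kind & e$confidence >= confidenceMin, , drop = FALSE]
  keep <- logical(nrow(e))
  if (nrow(e)) {
    isPPI <- e$kind == "ppi"
    keep[isPPI] <- e$source[isPPI] %in% genes & e$target[isPPI] %in% genes
    keep[!isPPI] <- e$target[!isPPI] %in% genes
  }
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  attach <- e[e$kind != "ppi" & !(e$source %in% genes), , drop = FALSE]
  nodeIds <- unique(c(genes[genes %in% c(e$source, e$target)], attach$source))
  type <- ifelse(nodeIds %in% genes, "input_gene",
                 ifelse(nodeIds %in% attach$source[attach$kind == "drug_target"],
                        "attached_drug", "attached_regulator"))
  nodes <- data.frame(id = nodeIds, type = type, inInput = nodeIds %in% genes,
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  new("InducedModule", nodes = nodes, edges = e, kinds = kind,
      confidenceMin = confidenceMin)
}

#' Run enrichment and network construction for each partition list
#'
#' Independently analyses the core, unique-A and unique-B gene lists:
#' over-representation against the collection, a pathway-overlap network,
#' and one induced module per interaction kind present. An empty gene list
#' yields empty results with a warning rather than an error.
#'
#' @param partition a [GenePartition-class].
#' @param collection a [GeneSetCollection-class].
#' @param interactions an [InteractionTable-class] (or `NULL` to skip
#'   modules).
#' @param universe gene universe for the hypergeometric test.
#' @param minOverlap,pCutoff,edgeMin,overlapBasis,confidenceMin passed to
#'   the underlying operations.
#' @return named list (`core`, `uniqueA`, `uniqueB`), each with elements
#'   `enrichment`, `pathwayNetwork`, `modules` (list by kind), or `NULL`
#'   entries for an empty input list.
#' @export
runThreeWay <- function(partition, collection, interactions, universe,
                        minOverlap = 2, pCutoff = 0.01, edgeMin = 0.30,
                        overlapBasis = "input_members", confidenceMin = 0.9) {
  lists <- list(core = partition@core, uniqueA = partition@uniqueA,
                uniqueB = partition@uniqueB)
  lapply(stats::setNames(names(lists), names(lists)), function(nm) {
    genes <- lists[[nm]]
    if (!length(genes)) {
      warning("empty gene list for '", nm, "'; returning empty results")
      return(list(enrichment = NULL, pathwayNetwork = NULL, modules = list()))
    }
    enr <- overrepresentation(genes, collection, universe,
                              minOverlap = minOverlap, pCutoff = pCutoff)
    net <- pathwayOverlapNetwork(enr, collection, edgeMin = edgeMin,
                                 overlapBasis = overlapBasis)
    mods <- list()
    if (!is.null(interactions)) {
      kinds <- unique(interactionEdges(interactions)$kind)
      mods <- lapply(stats::setNames(kinds, kinds), function(k)
        induceModule(genes, interactions, kind = k,
                     confidenceMin = confidenceMin))
    }
    list(enrichment = enr, pathwayNetwork = net, modules = mods)
  })
}

#' Export an InducedModule (or PathwayNetwork) as GraphML
#'
#' @param x an [InducedModule-class] or [PathwayNetwork-class].
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
writeModuleGraphML <- function(x, path) {
  if (is(x, "InducedModule")) {
    writeGraphML(x@nodes, x@edges, path)
  } else if (is(x, "PathwayNetwork")) {
    nodes <- data.frame(id = x@nodes$setId, type = "pathway",
                        p = x@nodes$p, q = x@nodes$q)
    edges <- data.frame(source = x@edges$setA, target = x@edges$setB,
                        overlapFraction = x@edges$overlapFraction)
    writeGraphML(nodes, edges, path)
  } else stop("unsupported object")
  invisible(path)
}
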