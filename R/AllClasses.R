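#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setOldClass("hclust")

.INTERACTION_KINDS <- c("ppi", "regulatory", "drug_target")
.INTERACTION_ROLES <- c("activator", "repressor", "product")

#' ExpressionMatrix: a genes-by-samples log2 expression container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"exprs"` assay of finite log2 intensities, with a mandatory
#' per-sample `group` column in `colData` (free diagnosis labels such as
#' `"TCMR"` or `"Neph"`; samples without a known group carry `"ungrouped"`).
#'
#' @slot .Data inherited SummarizedExperiment slots.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "exprs"))
    msg <- c(msg, "ExpressionMatrix must carry exactly one assay named 'exprs'")
  v <- SummarizedExperiment::assay(object, withDimnames = FALSE)
  if (!is.numeric(v))
    msg <- c(msg, "assay 'exprs' must be numeric")
  if (is.numeric(v) && !all(is.finite(v)))
    msg <- c(msg, "assay 'exprs' contains non-finite values")
  gid <- rownames(object); sid <- colnames(object)
  if (is.null(gid) || anyDuplicated(gid))
    msg <- c(msg, sprintf("duplicate or missing gene IDs%s",
      if (!is.null(gid)) paste0(": ", paste(unique(gid[duplicated(gid)])[1:min(3, sum(duplicated(gid)))], collapse = ", ")) else ""))
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "duplicate or missing sample IDs")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param groups optional named character vector mapping sample IDs to group
#'   labels; samples absent from the map are labelled `"ungrouped"`.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' sampleGroups(em)
#' @export
ExpressionMatrix <- function(values, groups = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  sid <- colnames(values)
  if (is.null(sid)) stop("expression matrix must have sample (column) names")
  grp <- rep("ungrouped", length(sid))
  names(grp) <- sid
  if (!is.null(groups)) {
    if (is.null(names(groups))) stop("'groups' must be a named character vector")
    hit <- intersect(sid, names(groups))
    grp[hit] <- as.character(groups[hit])
  }
  se <- SummarizedExperiment(
    assays = SimpleList(exprs = values),
    colData = DataFrame(group = unname(grp), row.names = sid))
  new("ExpressionMatrix", se)
}

#' GeneSetCollection: named gene sets read from GMT
#'
#' @slot setIds unique set identifiers.
#' @slot descriptions one free-text description per set.
#' @slot members list of character vectors of member gene IDs (unique within
#'   a set, every set non-empty).
#' @export
setClass("GeneSetCollection",
  representation(setIds = "character", descriptions = "character",
                 members = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  n <- length(object@setIds)
  if (anyDuplicated(object@setIds)) msg <- c(msg, "duplicate set IDs")
  if (length(object@descriptions) != n || length(object@members) != n)
    msg <- c(msg, "setIds, descriptions and members must have equal length")
  if (n && any(lengths(object@members) == 0L))
    msg <- c(msg, "every gene set must be non-empty")
  if (n && any(vapply(object@members, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "duplicate members within a set")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param members named list of character vectors (names become set IDs).
#' @param descriptions optional character vector of descriptions.
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(members, descriptions = NULL) {
  ids <- names(members)
  if (is.null(ids)) stop("'members' must be a named list")
  members <- lapply(members, function(m) unique(as.character(m)))
  if (is.null(descriptions)) descriptions <- rep("", length(members))
  new("GeneSetCollection", setIds = ids,
      descriptions = as.character(descriptions),
      members = unname(members))
}

#' InteractionTable: typed molecular interaction edges
#'
#' Edge list over genes/proteins, regulators and drugs. `ppi` edges are
#' undirected; `regulatory` and `drug_target` edges run source -> target.
#'
#' @slot edges data.frame with columns `source`, `target`, `kind`
#'   (`ppi`/`regulatory`/`drug_target`), `role`
#'   (`activator`/`repressor`/`product` or `NA`) and `confidence` in `[0,1]`.
#' @export
setClass("InteractionTable", representation(edges = "data.frame"))

setValidity("InteractionTable", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("source", "target", "kind", "role", "confidence")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$kind %in% .INTERACTION_KINDS))
      msg <- c(msg, sprintf("unknown interaction kind: %s",
                            paste(setdiff(unique(e$kind), .INTERACTION_KINDS), collapse = ", ")))
    bad <- !is.na(e$role) & !(e$role %in% .INTERACTION_ROLES)
    if (any(bad))
      msg <- c(msg, sprintf("unknown role token: %s",
                            paste(unique(e$role[bad]), collapse = ", ")))
    loops <- e$kind == "drug_target" & e$source == e$target
    if (any(loops))
      msg <- c(msg, sprintf("drug_target self-loop for node '%s'", e$source[which(loops)[1]]))
    if (any(!is.finite(e$confidence) | e$confidence < 0 | e$confidence > 1))
      msg <- c(msg, "confidence must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionTable
#'
#' @param source,target character vectors of endpoint IDs.
#' @param kind interaction kind per edge (recycled if scalar).
#' @param role optional role annotation per edge.
#' @param confidence optional confidence per edge, defaulting to 1.
#' @return an [InteractionTable-class].
#' @export
InteractionTable <- function(source = character(), target = character(),
                             kind = character(), role = NA_character_,
                             confidence = 1) {
  n <- length(source)
  e <- data.frame(source = as.character(source), target = as.character(target),
                  kind = rep_len(as.character(kind), n),
                  role = rep_len(as.character(role), n),
                  confidence = rep_len(as.numeric(confidence), n),
                  stringsAsFactors = FALSE)
  new("InteractionTable", edges = e)
}

#' EmbeddingReport: MDS coordinates with outlier flags
#'
#' @slot coordinates samples-by-d embedding coordinates (row names = sample IDs).
#' @slot center coordinates of the reference point (medoid or centroid).
#' @slot centerMode `"medoid"` or `"centroid"`.
#' @slot distances per-sample Euclidean distance to the center.
#' @slot zscores standardized distances (mean 0, sd 1 across samples).
#' @slot outliers sample IDs with z-score above the threshold.
#' @slot zThreshold the flagging threshold (default 2).
#' @slot degenerate TRUE when all distances were identical (no spread; no
#'   outliers can be flagged).
#' @export
setClass("EmbeddingReport",
  representation(coordinates = "matrix", center = "numeric",
                 centerMode = "character", distances = "numeric",
                 zscores = "numeric", outliers = "character",
                 zThreshold = "numeric", degenerate = "logical"))

#' ClusterSolution: merge tree, per-k labels and validity indices
#'
#' @slot tree the agglomerative merge tree as a [stats::hclust] object.
#' @slot labelsByK integer matrix, samples x candidate k (columns named by k);
#'   labels are renumbered by order of first appearance so cluster 1 contains
#'   the first sample.
#' @slot indices data.frame with columns `k`, `connectivity`, `dunn`,
#'   `silhouette`.
#' @slot votes named integer vector: the best k chosen by each index.
#' @slot selectedK the majority-vote cluster count (ties toward smallest k).
#' @export
setClass("ClusterSolution",
  representation(tree = "hclust", labelsByK = "matrix", indices = "data.frame",
                 votes = "integer", selectedK = "integer"))

setValidity("ClusterSolution", function(object) {
  msg <- character()
  ks <- as.integer(colnames(object@labelsByK))
  if (!(object@selectedK %in% ks))
    msg <- c(msg, "selectedK must be one of the evaluated k values")
  for (j in seq_along(ks)) {
    lab <- object@labelsByK[, j]
    if (length(unique(lab)) != ks[j])
      msg <- c(msg, sprintf("labels for k=%d do not form %d non-empty clusters", ks[j], ks[j]))
  }
  if (length(msg)) msg else TRUE
})

#' DEResult: per-gene two-group differential expression
#'
#' @slot table data.frame with one row per gene: `gene`, `mean1`, `mean2`,
#'   `t`, `p`, `q`, `direction` (`up` = group1 above group2), `degenerate`
#'   (zero variance in both groups with unequal means; `p` is the 0 sentinel).
#' @slot groups the two group labels compared, in order (group1, group2).
#' @slot alpha significance cutoff applied to `q` (or `p`, see `gate`).
#' @slot gate `"q"` or `"p"`: which column the cutoff was applied to.
#' @slot significant gene IDs passing the gate.
#' @export
setClass("DEResult",
  representation(table = "data.frame", groups = "character", alpha = "numeric",
                 gate = "character", significant = "character"))

#' GenePartition: core and subtype-unique differential gene sets
#'
#' `core` = DE in both subtype-vs-control contrasts; `uniqueA`/`uniqueB` = DE
#' in exactly one. The three sets are pairwise disjoint by construction.
#'
#' @slot core,uniqueA,uniqueB character vectors of gene IDs.
#' @export
setClass("GenePartition",
  representation(core = "character", uniqueA = "character",
                 uniqueB = "character"))

setValidity("GenePartition", function(object) {
  s <- list(object@core, object@uniqueA, object@uniqueB)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(s[[i]], s[[j]])))
      return("core/uniqueA/uniqueB must be pairwise disjoint")
  TRUE
})

#' EnrichmentResult: hypergeometric over-representation table
#'
#' @slot table reported sets (overlap and p filters applied), sorted by p:
#'   `setId`, `description`, `nUniverse`, `nSet`, `nInput`, `nOverlap`, `p`,
#'   `q`, `overlapGenes` (semicolon-joined).
#' @slot allTested the same statistics for every tested set, unfiltered
#'   (q-values are computed over this table).
#' @slot parameters list: universe size, minOverlap, pCutoff.
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", allTested = "data.frame",
                 parameters = "list"))

#' PathwayNetwork: overlap graph over enriched gene sets
#'
#' @slot nodes data.frame of enriched sets (`setId`, `p`, `q`, `nOverlap`).
#' @slot edges data.frame `setA`, `setB`, `overlapFraction` (undirected; one
#'   row per unordered pair with fraction >= the edge threshold).
#' @slot edgeMin the minimum overlap fraction used.
#' @slot overlapBasis `"input_members"` or `"all_members"`.
#' @export
setClass("PathwayNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 edgeMin = "numeric", overlapBasis = "character"))

#' InducedModule: interaction subgraph anchored on an input gene list
#'
#' @slot nodes data.frame `id`, `type` (`input_gene`, `attached_regulator`,
#'   `attached_drug`), `inInput` (logical).
#' @slot edges surviving interaction edges (`source`, `target`, `kind`,
#'   `role`, `confidence`).
#' @slot kinds interaction kinds included.
#' @slot confidenceMin the high-confidence threshold applied.
#' @export
setClass("InducedModule",
  representation(nodes = "data.frame", edges = "data.frame",
                 kinds = "character", confidenceMin = "numeric"))

#' SyntheticConfig: parameters of the planted-truth generator
#'
#' Defaults emulate the cohort structure the pipeline targets: two rejection
#' subtypes of 14 biopsies each (28 retained of 31), 3 outlier biopsies, 8
#' nephrectomy-style controls, and three planted differential gene classes
#' (core, unique-A, unique-B) on a 2000-gene background.
#'
#' @slot nGenes total genes (default 2000).
#' @slot nPerSubtype samples per subtype (default 14).
#' @slot nControl control samples (default 8).
#' @slot nOutliers planted outlier samples, counted within the case group
#'   (default 3).
#' @slot fracCore,fracUniqueA,fracUniqueB fractions of genes in each planted
#'   class (defaults 0.05, 0.03, 0.03; must sum below 1).
#' @slot effectSize mean shift of planted genes in affected groups, in units
#'   of `noiseSd` (default 2.0 log2 units).
#' @slot outlierShift extra shift applied to outlier samples on a random half
#'   of genes (default 6.0 sd units).
#' @slot noiseSd per-gene Gaussian noise sd on the log2 scale (default 1.0).
#' @slot baselineRange range of per-gene baseline means for background genes
#'   (default [4, 12] log2 units); planted genes draw from [4.5, 6] so the
#'   default expression/CV filter retains them.
#' @slot seed integer RNG seed; fixed seed gives bit-identical output.
#' @export
setClass("SyntheticConfig",
  representation(nGenes = "integer", nPerSubtype = "integer",
                 nControl = "integer", nOutliers = "integer",
                 fracCore = "numeric", fracUniqueA = "numeric",
                 fracUniqueB = "numeric", effectSize = "numeric",
                 outlierShift = "numeric", noiseSd = "numeric",
                 baselineRange = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@fracCore + object@fracUniqueA + object@fracUniqueB >= 1)
    msg <- c(msg, "planted gene fractions must sum below 1")
  if (any(c(object@nGenes, object@nPerSubtype, object@nControl) <= 0L))
    msg <- c(msg, "counts must be positive")
  if (object@nOutliers < 0L) msg <- c(msg, "nOutliers must be >= 0")
  if (any(c(object@fracCore, object@fracUniqueA, object@fracUniqueB) < 0))
    msg <- c(msg, "fractions must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (length(object@baselineRange) != 2L || diff(object@baselineRange) <= 0)
    msg <- c(msg, "baselineRange must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot subtype named character: planted subtype (`"A"`/`"B"`) per case
#'   sample; controls are absent from this map.
#' @slot outliers sample IDs of planted outliers.
#' @slot geneClass named character: `core`, `unique_a`, `unique_b` or `null`
#'   per gene.
#' @slot config the [SyntheticConfig-class] that produced the dataset.
#' @export
setClass("GroundTruth",
  representation(subtype = "character", outliers = "character",
                 geneClass = "character", config = "SyntheticConfig"))
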