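#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs. All
#' cells must be numeric; readers reject malformed input rather than
#' repairing it, naming the offending line or ID.
#'
#' @param path path to the expression TSV.
#' @param groupPath optional two-column TSV (sample_id, group) mapping
#'   samples to diagnosis labels; unmapped samples get `"ungrouped"`.
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionTSV <- function(path, groupPath = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("format error in '", path, "': empty or header-only expression file")
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  gid <- tab[[1]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("format error: duplicate gene ID '", dup[1], "'")
  sid <- colnames(tab)[-1]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("format error: non-numeric or missing value at gene '%s', sample '%s'",
                 gid[bad[1, 1]], sid[bad[1, 2]]))
  dimnames(num) <- list(gid, sid)
  groups <- if (!is.null(groupPath)) readGroupsTSV(groupPath) else NULL
  ExpressionMatrix(num, groups)
}

#' Read a two-column sample-to-group map
#'
#' @param path TSV with columns sample_id, group (no header required; a
#'   header line is detected and skipped when its first field is
#'   `sample_id`).
#' @return named character vector of group labels.
#' @export
readGroupsTSV <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("format error: group map needs two columns")
  if (tolower(tab[1, 1]) %in% c("sample_id", "sample"))
    tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write an ExpressionMatrix (and optionally its group map) as TSV
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output TSV path.
#' @param groupPath optional path for the sample-to-group map.
#' @param digits significant digits used for serialization (default 6, for
#'   reproducible diffs).
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(x, path, groupPath = NULL, digits = 6) {
  v <- exprValues(x)
  out <- data.frame(gene_id = rownames(v),
                    signif(v, digits), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groupPath)) {
    g <- sampleGroups(x)
    utils::write.table(data.frame(sample_id = names(g), group = unname(g)),
                       groupPath, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a GEO-style series-matrix text file
#'
#' Parses the plain-text series-matrix layout: `!`-prefixed metadata lines
#' and an expression table fenced by `!series_matrix_table_begin` /
#' `!series_matrix_table_end`. When `groupKey` is given (e.g. `"diagnosis"`),
#' `!Sample_characteristics_ch1` entries of the form `key: value` matching it
#' supply the sample group labels.
#'
#' @param path path to the series-matrix file.
#' @param groupKey optional characteristics key to harvest group labels from.
#' @return an [ExpressionMatrix-class].
#' @export
readSeriesMatrix <- function(path, groupKey = NULL) {
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
    stop("format error in '", path,
         "': missing !series_matrix_table_begin/!series_matrix_table_end delimiters")
  tabLines <- gsub('"', "", lines[(b + 1L):(e - 1L)], fixed = TRUE)
  tab <- utils::read.delim(text = tabLines, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  gid <- tab[[1]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) stop("format error: duplicate probe ID '", dup[1], "'")
  sid <- colnames(tab)[-1]
  vals <- suppressWarnings(matrix(as.numeric(as.matrix(tab[, -1, drop = FALSE])),
                                  length(gid), length(sid)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("format error: non-numeric value at probe '%s', sample '%s'",
                 gid[bad[1, 1]], sid[bad[1, 2]]))
  dimnames(vals) <- list(gid, sid)
  groups <- NULL
  if (!is.null(groupKey)) {
    ch <- lines[grep("^!Sample_characteristics_ch", lines)]
    for (ln in ch) {
      fields <- gsub('"', "", strsplit(ln, "\t", fixed = TRUE)[[1]][-1])
      hit <- grepl(paste0("^", groupKey, "\\s*:"), fields)
      if (any(hit)) {
        lab <- trimws(sub(paste0("^", groupKey, "\\s*:"), "", fields))
        lab[!hit] <- "ungrouped"
        groups <- stats::setNames(lab[seq_along(sid)], sid)
        break
      }
    }
  }
  ExpressionMatrix(vals, groups)
}

#' Read a GMT gene-set file
#'
#' One set per line: `set_id TAB description TAB member TAB member ...`.
#' Duplicate members within a line are collapsed.
#'
#' @param path GMT path.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("format error: GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("format error: duplicate gene-set ID '", dup[1], "'")
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  GeneSetCollection(members, vapply(fields, `[[`, "", 2L))
}

#' Write a GeneSetCollection as GMT
#'
#' @param x a [GeneSetCollection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(seq_along(x@setIds), function(i)
    paste(c(x@setIds[i], x@descriptions[i], x@members[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-delimited interaction edge list
#'
#' Columns: source, target, then optionally role and/or confidence (a numeric
#' third column is taken as confidence). Confidence defaults to 1.
#'
#' @param path edge-list path.
#' @param kind interaction kind for all edges: `"ppi"`, `"regulatory"` or
#'   `"drug_target"`.
#' @return an [InteractionTable-class].
#' @export
readInteractions <- function(path, kind = c("ppi", "regulatory", "drug_target")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (tolower(tab[1, 1]) %in% c("source", "from"))
    tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2L) stop("format error: interaction table needs >= 2 columns")
  role <- rep(NA_character_, nrow(tab))
  conf <- rep(1, nrow(tab))
  if (ncol(tab) >= 3L) {
    third <- tab[[3]]
    asNum <- suppressWarnings(as.numeric(third))
    if (all(is.finite(asNum))) conf <- asNum else role <- third
  }
  if (ncol(tab) >= 4L) {
    conf4 <- suppressWarnings(as.numeric(tab[[4]]))
    if (any(!is.finite(conf4)))
      stop("format error: non-numeric confidence at line ",
           which(!is.finite(conf4))[1])
    conf <- conf4
  }
  role[!is.na(role) & role == ""] <- NA_character_
  InteractionTable(tab[[1]], tab[[2]], kind, role, conf)
}

#' Write an InteractionTable as TSV
#'
#' @param x an [InteractionTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInteractions <- function(x, path) {
  e <- x@edges
  out <- data.frame(e$source, e$target,
                    ifelse(is.na(e$role), "", e$role), e$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene symbols
#'
#' Optional step for array data measured at probe level: keeps, per gene
#' symbol, the probe with the highest coefficient of variation (the most
#' informative probe under the pipeline's CV-centric filtering).
#'
#' @param x an [ExpressionMatrix-class] with probe IDs in rows.
#' @param map named character vector probe_id -> gene symbol (probes missing
#'   from the map are dropped).
#' @param strategy collapsing rule; only `"highest_cv"` is implemented.
#' @return an [ExpressionMatrix-class] with gene symbols as row IDs.
#' @export
collapseProbes <- function(x, map, strategy = c("highest_cv")) {
  strategy <- match.arg(strategy)
  v <- exprValues(x)
  keep <- intersect(rownames(v), names(map))
  if (!length(keep)) stop("no probes of 'x' found in 'map'")
  v <- v[keep, , drop = FALSE]
  sym <- as.character(map[keep])
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, -Inf)
  ord <- order(sym, -cv)
  first <- !duplicated(sym[ord])
  sel <- ord[first]
  out <- v[sel, , drop = FALSE]
  rownames(out) <- sym[sel]
  ExpressionMatrix(out, sampleGroups(x))
}

#' Write a node/edge table pair as GraphML
#'
#' @param nodes data.frame with an `id` column (unique) plus scalar
#'   attribute columns; a `type` column (gene/pathway/drug/tf) is preserved
#'   like any other attribute.
#' @param edges data.frame with `source` and `target` columns referring to
#'   node IDs, plus scalar attribute columns.
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(nodes, edges, path) {
  if (!"id" %in% colnames(nodes)) stop("'nodes' must have an 'id' column")
  dup <- unique(nodes$id[duplicated(nodes$id)])
  if (length(dup)) stop("duplicate node ID '", dup[1], "'")
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown))
      stop("edge references unknown node '", unknown[1], "'")
  }
  ed <- if (nrow(edges)) {
    data.frame(from = edges$source, to = edges$target,
               edges[, setdiff(colnames(edges), c("source", "target")),
                     drop = FALSE])
  } else data.frame(from = character(), to = character())
  nd <- data.frame(name = nodes$id,
                   nodes[, setdiff(colnames(nodes), "id"), drop = FALSE])
  # drop NA-typed attribute columns GraphML cannot carry as scalars
  for (cn in colnames(nd)) if (all(is.na(nd[[cn]]))) nd[[cn]] <- NULL
  for (cn in colnames(ed)) if (cn %in% c("from", "to")) next else
    if (all(is.na(ed[[cn]]))) ed[[cn]] <- NULL
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write an edge list in SIF format (source TAB kind TAB target)
#'
#' @param edges data.frame with `source`, `target` and `kind` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(edges, path) {
  lines <- if (nrow(edges))
    paste(edges$source, edges$kind, edges$target, sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}
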