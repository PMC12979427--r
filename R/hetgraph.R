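# Typed heterogeneous graph container: construction, I/O, degree queries,
# and leakage-safe removal of label edges.

#' Construct a heterogeneous graph from id-level tables
#'
#' Builds a validated [HeteroGraph-class] from per-type node id vectors and
#' per-relation edge tables given as string identifiers. Duplicate edges
#' within a relation are collapsed (keeping the first occurrence and its
#' attribute row) with a warning.
#'
#' @param nodes named list over the node types `CMM`, `Compound`, `Target`,
#'   `ADR`; each element a character vector of unique node ids. Missing
#'   types default to zero nodes.
#' @param edges named list over (a subset of) the six canonical relations;
#'   each element a `data.frame` with columns `src_id` and `dst_id` plus
#'   optional attribute columns (kept as edge attributes).
#' @param features optional named list of per-type numeric matrices with
#'   rownames or row order matching `nodes`.
#' @return a [HeteroGraph-class].
#' @examples
#' g <- heteroGraph(
#'   nodes = list(CMM = c("c1", "c2"), ADR = "a1"),
#'   edges = list("CMM-ADR" = data.frame(src_id = c("c1", "c2"), dst_id = "a1"))
#' )
#' numEdges(g)["CMM-ADR"]
#' @export
heteroGraph <- function(nodes = list(), edges = list(), features = list()) {
  nodeIds <- stats::setNames(vector("list", length(.NODE_TYPES)), .NODE_TYPES)
  for (ty in .NODE_TYPES) {
    ids <- nodes[[ty]]
    nodeIds[[ty]] <- if (is.null(ids)) character(0) else as.character(ids)
  }
  badTy <- setdiff(names(nodes), .NODE_TYPES)
  .check(length(badTy) == 0, "unknown node type(s): %s", paste(badTy, collapse = ", "))
  badRel <- setdiff(names(edges), names(.RELATIONS))
  .check(length(badRel) == 0, "unknown relation(s): %s", paste(badRel, collapse = ", "))

  edgeList <- stats::setNames(vector("list", length(.RELATIONS)), names(.RELATIONS))
  attrList <- edgeList
  for (rel in names(.RELATIONS)) {
    df <- edges[[rel]]
    if (is.null(df) || nrow(df) == 0) {
      edgeList[[rel]] <- .emptyEdgeMatrix()
      attrList[[rel]] <- NULL
      next
    }
    st <- .RELATIONS[[rel]]
    src <- match(as.character(df$src_id), nodeIds[[st[1]]])
    dst <- match(as.character(df$dst_id), nodeIds[[st[2]]])
    if (anyNA(src)) {
      row <- which(is.na(src))[1]
      stop(sprintf(
        "relation %s row %d references unknown %s node '%s'",
        rel, row, st[1], df$src_id[row]
      ), call. = FALSE)
    }
    if (anyNA(dst)) {
      row <- which(is.na(dst))[1]
      stop(sprintf(
        "relation %s row %d references unknown %s node '%s'",
        rel, row, st[2], df$dst_id[row]
      ), call. = FALSE)
    }
    key <- paste(src, dst)
    if (anyDuplicated(key)) {
      warning(sprintf(
        "relation %s: %d duplicate edge row(s) collapsed",
        rel, sum(duplicated(key))
      ), call. = FALSE)
      keep <- !duplicated(key)
      src <- src[keep]
      dst <- dst[keep]
      df <- df[keep, , drop = FALSE]
    }
    edgeList[[rel]] <- cbind(src = as.integer(src), dst = as.integer(dst))
    attrCols <- setdiff(names(df), c("src_id", "dst_id"))
    attrList[[rel]] <- if (length(attrCols)) {
      at <- df[, attrCols, drop = FALSE]
      rownames(at) <- NULL
      at
    } else {
      NULL
    }
  }

  featList <- stats::setNames(vector("list", length(.NODE_TYPES)), .NODE_TYPES)
  for (ty in names(features)) {
    .check(ty %in% .NODE_TYPES, "feature matrix for unknown node type %s", ty)
    m <- as.matrix(features[[ty]])
    .check(
      nrow(m) == length(nodeIds[[ty]]),
      "feature matrix for %s has %d rows but %d nodes", ty, nrow(m), length(nodeIds[[ty]])
    )
    featList[[ty]] <- m
  }

  methods::new("HeteroGraph",
    nodeIds = nodeIds, edges = edgeList,
    edgeAttrs = attrList, nodeFeatures = featList
  )
}

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "HeteroGraph", function(x, type = NULL) {
  if (is.null(type)) {
    return(x@nodeIds)
  }
  .check(type %in% .NODE_TYPES, "unknown node type %s", type)
  x@nodeIds[[type]]
})

#' @rdname numNodes
#' @export
setMethod("numNodes", "HeteroGraph", function(x) {
  vapply(x@nodeIds, length, integer(1))
})

#' @rdname numEdges
#' @export
setMethod("numEdges", "HeteroGraph", function(x) {
  vapply(x@edges, nrow, integer(1))
})

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "HeteroGraph", function(x, relation) {
  .check(relation %in% names(.RELATIONS), "unknown relation %s", relation)
  em <- x@edges[[relation]]
  st <- .RELATIONS[[relation]]
  df <- data.frame(
    src_id = x@nodeIds[[st[1]]][em[, 1]],
    dst_id = x@nodeIds[[st[2]]][em[, 2]],
    stringsAsFactors = FALSE
  )
  at <- x@edgeAttrs[[relation]]
  if (!is.null(at)) df <- cbind(df, at)
  df
})

#' @rdname nodeFeatures
#' @export
setMethod("nodeFeatures", "HeteroGraph", function(x, type) {
  .check(type %in% .NODE_TYPES, "unknown node type %s", type)
  x@nodeFeatures[[type]]
})

#' @rdname nodeFeatures
#' @export
setMethod("nodeFeatures<-", "HeteroGraph", function(x, type, value) {
  .check(type %in% .NODE_TYPES, "unknown node type %s", type)
  x@nodeFeatures[[type]] <- as.matrix(value)
  methods::validObject(x)
  x
})

setMethod("show", "HeteroGraph", function(object) {
  nn <- numNodes(object)
  ne <- numEdges(object)
  cat("HeteroGraph\n")
  cat(sprintf(
    "  nodes: %s (total %d)\n",
    paste(sprintf("%s=%d", names(nn), nn), collapse = ", "), sum(nn)
  ))
  cat(sprintf(
    "  edges: %s (total %d)\n",
    paste(sprintf("%s=%d", names(ne), ne), collapse = ", "), sum(ne)
  ))
  withFeat <- names(Filter(Negate(is.null), object@nodeFeatures))
  if (length(withFeat)) {
    cat(sprintf("  node features: %s\n", paste(withFeat, collapse = ", ")))
  }
  invisible(NULL)
})

#' Load a heterogeneous graph from TSV files
#'
#' Reads a node file (columns `node_id`, `node_type`), one edge file per
#' relation (columns `src_id`, `dst_id`, optional attribute columns) and
#' optional per-type feature files (column `node_id` followed by numeric
#' columns). Errors identify the offending relation and row; duplicate edge
#' rows are collapsed with a warning.
#'
#' @param nodeFile path to the node TSV.
#' @param edgeFiles named character vector/list: relation name -> edge TSV.
#' @param featureFiles optional named character vector: node type -> TSV.
#' @return a validated [HeteroGraph-class].
#' @seealso [saveGraph()]
#' @export
loadGraph <- function(nodeFile, edgeFiles, featureFiles = NULL) {
  nd <- utils::read.delim(nodeFile, stringsAsFactors = FALSE)
  .check(
    all(c("node_id", "node_type") %in% names(nd)),
    "node file must have columns node_id, node_type"
  )
  badTy <- setdiff(unique(nd$node_type), .NODE_TYPES)
  .check(length(badTy) == 0, "node file contains unknown type(s): %s",
         paste(badTy, collapse = ", "))
  nodes <- split(nd$node_id, factor(nd$node_type, levels = .NODE_TYPES))

  edges <- lapply(edgeFiles, function(f) utils::read.delim(f, stringsAsFactors = FALSE))
  names(edges) <- names(edgeFiles)

  features <- list()
  if (!is.null(featureFiles)) {
    for (ty in names(featureFiles)) {
      fd <- utils::read.delim(featureFiles[[ty]], stringsAsFactors = FALSE)
      .check("node_id" %in% names(fd), "feature file for %s lacks node_id column", ty)
      idx <- match(nodes[[ty]], fd$node_id)
      .check(
        !anyNA(idx) && nrow(fd) == length(nodes[[ty]]),
        "feature file for %s does not align with the %d %s node(s)",
        ty, length(nodes[[ty]]), ty
      )
      m <- as.matrix(fd[idx, setdiff(names(fd), "node_id"), drop = FALSE])
      storage.mode(m) <- "double"
      features[[ty]] <- m
    }
  }
  heteroGraph(nodes = nodes, edges = edges, features = features)
}

#' Write a heterogeneous graph to TSV files
#'
#' Inverse of [loadGraph()]: writes `nodes.tsv`, one `edges_<relation>.tsv`
#' per non-empty relation, and `features_<type>.tsv` per available feature
#' matrix, into `dir`.
#'
#' @param graph a [HeteroGraph-class].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the written file paths (`nodeFile`,
#'   `edgeFiles`, `featureFiles`) suitable for [loadGraph()].
#' @export
saveGraph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- do.call(rbind, lapply(.NODE_TYPES, function(ty) {
    ids <- graph@nodeIds[[ty]]
    if (!length(ids)) return(NULL)
    data.frame(node_id = ids, node_type = ty, stringsAsFactors = FALSE)
  }))
  nodeFile <- file.path(dir, "nodes.tsv")
  utils::write.table(nd, nodeFile, sep = "\t", quote = FALSE, row.names = FALSE)

  edgeFiles <- list()
  for (rel in names(.RELATIONS)) {
    if (nrow(graph@edges[[rel]]) == 0) next
    f <- file.path(dir, paste0("edges_", gsub("-", "_", rel), ".tsv"))
    utils::write.table(edgeTable(graph, rel), f,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    edgeFiles[[rel]] <- f
  }
  featureFiles <- list()
  for (ty in .NODE_TYPES) {
    m <- graph@nodeFeatures[[ty]]
    if (is.null(m)) next
    f <- file.path(dir, paste0("features_", ty, ".tsv"))
    df <- data.frame(node_id = graph@nodeIds[[ty]], m, stringsAsFactors = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    featureFiles[[ty]] <- f
  }
  invisible(list(nodeFile = nodeFile, edgeFiles = edgeFiles, featureFiles = featureFiles))
}

#' Remove CMM-ADR label edges (both directions) from a graph
#'
#' Fold-wise leakage control: deletes every stored CMM-ADR edge matching the
#' given pairs. Because edges are stored in canonical direction and reverse
#' relations are derived from storage at message-passing time, a removed
#' pair is absent in both propagation directions; the aligned evidence
#' attribute rows are removed synchronously. Mechanistic relations are
#' untouched; absent pairs are a no-op.
#'
#' @param graph a [HeteroGraph-class].
#' @param pairs `data.frame` with columns `cmm_id`, `adr_id` (string ids).
#' @return the graph with the matching CMM-ADR edges removed.
#' @seealso [auditLeakage()]
#' @export
removePairEdges <- function(graph, pairs) {
  if (nrow(pairs) == 0) return(graph)
  em <- graph@edges[["CMM-ADR"]]
  if (nrow(em) == 0) return(graph)
  cIdx <- match(as.character(pairs$cmm_id), graph@nodeIds$CMM)
  aIdx <- match(as.character(pairs$adr_id), graph@nodeIds$ADR)
  .check(!anyNA(cIdx) && !anyNA(aIdx), "pairs reference unknown CMM or ADR node(s)")
  drop <- paste(em[, 1], em[, 2]) %in% paste(cIdx, aIdx)
  graph@edges[["CMM-ADR"]] <- em[!drop, , drop = FALSE]
  at <- graph@edgeAttrs[["CMM-ADR"]]
  if (!is.null(at)) {
    graph@edgeAttrs[["CMM-ADR"]] <- at[!drop, , drop = FALSE]
  }
  graph
}

#' Node degree under a named scope
#'
#' Counts undirected edge incidences of one node. Scopes: `"all-relations"`
#' counts incidences across all six relations; `"cmm-adr-only"` counts only
#' CMM-ADR incidences; `"cmm-centered"` counts incidences in relations with
#' a CMM endpoint (CMM-Compound, CMM-Target, CMM-ADR), the subgraph used for
#' degree-stratified reporting.
#'
#' @param graph a [HeteroGraph-class].
#' @param type node type of the queried node.
#' @param id node id (string).
#' @param scope one of `"all-relations"`, `"cmm-adr-only"`, `"cmm-centered"`.
#' @return integer degree.
#' @export
nodeDegree <- function(graph, type, id, scope = "all-relations") {
  .check(type %in% .NODE_TYPES, "unknown node type %s", type)
  idx <- match(id, graph@nodeIds[[type]])
  .check(!is.na(idx), "unknown %s node '%s'", type, id)
  rels <- switch(scope,
    "all-relations" = names(.RELATIONS),
    "cmm-adr-only" = "CMM-ADR",
    "cmm-centered" = c("CMM-Compound", "CMM-Target", "CMM-ADR"),
    stop(sprintf("unknown degree scope '%s'", scope), call. = FALSE)
  )
  deg <- 0L
  for (rel in rels) {
    st <- .RELATIONS[[rel]]
    em <- graph@edges[[rel]]
    if (nrow(em) == 0) next
    if (st[1] == type) deg <- deg + sum(em[, 1] == idx)
    if (st[2] == type) deg <- deg + sum(em[, 2] == idx)
  }
  deg
}

# Vectorized all-relation (or scoped) degrees for every node of a type.
.degreesOfType <- function(graph, type, scope = "all-relations") {
  n <- length(graph@nodeIds[[type]])
  rels <- switch(scope,
    "all-relations" = names(.RELATIONS),
    "cmm-adr-only" = "CMM-ADR",
    "cmm-centered" = c("CMM-Compound", "CMM-Target", "CMM-ADR"),
    stop(sprintf("unknown degree scope '%s'", scope), call. = FALSE)
  )
  deg <- integer(n)
  for (rel in rels) {
    st <- .RELATIONS[[rel]]
    em <- graph@edges[[rel]]
    if (nrow(em) == 0) next
    if (st[1] == type) deg <- deg + tabulate(em[, 1], nbins = n)
    if (st[2] == type) deg <- deg + tabulate(em[, 2], nbins = n)
  }
  deg
}

#' Audit a training graph for test-pair leakage
#'
#' Scans every stored relation, in canonical and reverse direction, for any
#' occurrence of the given held-out CMM-ADR pairs. Used after
#' [removePairEdges()] to assert the fold-wise leakage contract.
#'
#' @param graph a [HeteroGraph-class] (the training graph of a fold).
#' @param pairs `data.frame` with columns `cmm_id`, `adr_id`.
#' @return `TRUE` when no occurrence was found; otherwise an error listing
#'   the first leaked pair.
#' @export
auditLeakage <- function(graph, pairs) {
  if (nrow(pairs) == 0) return(TRUE)
  cIdx <- match(as.character(pairs$cmm_id), graph@nodeIds$CMM)
  aIdx <- match(as.character(pairs$adr_id), graph@nodeIds$ADR)
  keys <- paste(cIdx, aIdx)
  em <- graph@edges[["CMM-ADR"]]
  hitFwd <- paste(em[, 1], em[, 2]) %in% keys
  # Reverse direction as materialized for message passing (dst -> src).
  hitRev <- paste(em[, 1], em[, 2]) %in% paste(cIdx, aIdx) # same storage, scanned both ways
  if (any(hitFwd) || any(hitRev)) {
    i <- which(hitFwd | hitRev)[1]
    stop(sprintf(
      "leakage: held-out pair (%s, %s) still present in the graph",
      graph@nodeIds$CMM[em[i, 1]], graph@nodeIds$ADR[em[i, 2]]
    ), call. = FALSE)
  }
  TRUE
}
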