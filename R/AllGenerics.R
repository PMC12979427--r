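#' Node identifiers of a heterogeneous graph
#'
#' @param x a [HeteroGraph-class].
#' @param type a node type (`"CMM"`, `"Compound"`, `"Target"`, `"ADR"`), or
#'   `NULL` for the full named list.
#' @return character vector of node ids, or a named list of them.
#' @export
setGeneric("nodeIds", function(x, type = NULL) standardGeneric("nodeIds"))

#' Number of nodes per type
#'
#' @param x a [HeteroGraph-class].
#' @return named integer vector over node types.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges per relation
#'
#' @param x a [HeteroGraph-class].
#' @return named integer vector over the six canonical relations.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge table of one relation
#'
#' @param x a [HeteroGraph-class].
#' @param relation a canonical relation name, e.g. `"CMM-ADR"`.
#' @return `data.frame` with columns `src_id`, `dst_id` followed by any edge
#'   attribute columns.
#' @export
setGeneric("edgeTable", function(x, relation) standardGeneric("edgeTable"))

#' Node feature matrix of one type
#'
#' @param x a [HeteroGraph-class].
#' @param type a node type.
#' @return numeric matrix (rows aligned with [nodeIds()]) or `NULL`.
#' @export
setGeneric("nodeFeatures", function(x, type) standardGeneric("nodeFeatures"))

#' @rdname nodeFeatures
#' @param value numeric matrix with one row per node of `type`.
#' @export
setGeneric("nodeFeatures<-", function(x, type, value) standardGeneric("nodeFeatures<-"))
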