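#' @import methods
NULL

#' Typed heterogeneous pharmacovigilance graph
#'
#' Container for the four-node-type graph underlying CMM--ADR link
#' prediction: Chinese Materia Medica (CMM), chemical compounds, protein
#' targets and adverse drug reactions (ADR, MedDRA Preferred Terms).
#' Six canonical relations are stored: CMM-Compound, Compound-Target,
#' CMM-Target, Target-Target, Target-ADR and CMM-ADR. Edges are stored in
#' canonical direction only; message passing materializes the reverse
#' relations on the fly, and edge removal is always effective in both
#' directions.
#'
#' @slot nodeIds named list (one element per node type) of character vectors
#'   of node identifiers, in storage order.
#' @slot edges named list (one element per relation) of two-column integer
#'   matrices of 1-based node indices (`src`, `dst`) into the respective
#'   type's `nodeIds`.
#' @slot edgeAttrs named list of per-relation `data.frame`s of edge
#'   attributes (row-aligned with `edges`), or `NULL` where a relation
#'   carries no attributes. CMM-ADR edges typically carry `report_count`
#'   and `provenance`.
#' @slot nodeFeatures named list of per-type numeric feature matrices
#'   (rows aligned with `nodeIds`), or `NULL` where absent.
#'
#' @seealso [heteroGraph()], [loadGraph()], [removePairEdges()],
#'   [nodeDegree()]
#' @export
setClass("HeteroGraph",
  representation(
    nodeIds = "list",
    edges = "list",
    edgeAttrs = "list",
    nodeFeatures = "list"
  )
)

setValidity("HeteroGraph", function(object) {
  msgs <- character(0)
  if (!identical(names(object@nodeIds), .NODE_TYPES)) {
    return("nodeIds must be a named list over types CMM, Compound, Target, ADR")
  }
  if (!identical(names(object@edges), names(.RELATIONS))) {
    return("edges must be a named list over the six canonical relations")
  }
  for (ty in .NODE_TYPES) {
    ids <- object@nodeIds[[ty]]
    if (anyDuplicated(ids)) {
      msgs <- c(msgs, sprintf("duplicate node ids for type %s", ty))
    }
    feat <- object@nodeFeatures[[ty]]
    if (!is.null(feat) && nrow(feat) != length(ids)) {
      msgs <- c(msgs, sprintf(
        "feature matrix for type %s has %d rows but %d nodes",
        ty, nrow(feat), length(ids)
      ))
    }
  }
  for (rel in names(.RELATIONS)) {
    em <- object@edges[[rel]]
    if (!is.matrix(em) || ncol(em) != 2L) {
      msgs <- c(msgs, sprintf("edges for %s must be a 2-column matrix", rel))
      next
    }
    st <- .RELATIONS[[rel]]
    nSrc <- length(object@nodeIds[[st[1]]])
    nDst <- length(object@nodeIds[[st[2]]])
    if (nrow(em) > 0) {
      if (min(em) < 1L || max(em[, 1]) > nSrc || max(em[, 2]) > nDst) {
        msgs <- c(msgs, sprintf("edge endpoints out of range in relation %s", rel))
      }
      if (anyDuplicated(paste(em[, 1], em[, 2]))) {
        msgs <- c(msgs, sprintf("duplicate (src,dst) edge in relation %s", rel))
      }
    }
    at <- object@edgeAttrs[[rel]]
    if (!is.null(at) && nrow(at) != nrow(em)) {
      msgs <- c(msgs, sprintf(
        "edge attributes for %s have %d rows but %d edges", rel, nrow(at), nrow(em)
      ))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Min-max evidence feature scaler
#'
#' Per-feature min/max ranges fitted on the training fold's CMM--ADR edges,
#' used to map the count-like evidence features (log report count, node
#' degrees, meta-path score) to \[0,1\]. Transforms of held-out edges are
#' clamped to \[0,1\].
#'
#' @slot featureNames character vector of scaled feature names.
#' @slot mins,maxs numeric vectors of fitted per-feature minima/maxima.
#' @slot fitted logical scalar.
#' @seealso [fitEvidenceScaler()], [buildEvidenceVectors()]
#' @export
setClass("EvidenceScaler",
  representation(
    featureNames = "character",
    mins = "numeric",
    maxs = "numeric",
    fitted = "logical"
  ),
  prototype(fitted = FALSE)
)

setValidity("EvidenceScaler", function(object) {
  if (object@fitted &&
      (length(object@mins) != length(object@featureNames) ||
       length(object@maxs) != length(object@featureNames))) {
    return("fitted scaler must carry one min and max per feature")
  }
  TRUE
})

#' Ordered MedDRA-to-TCM mapping rule set
#'
#' Rule-based mapping of MedDRA Preferred Terms (PT), with their System
#' Organ Class (SOC), to Traditional Chinese Medicine functional systems.
#' Exact-PT rules take precedence over SOC defaults; unmatched terms are
#' reported as unmapped, never dropped.
#'
#' @slot systems character vector of the functional-system vocabulary
#'   (16 categories in the shipped default rule set: five Zang organs plus
#'   the Pericardium, six Fu organs, Body Surface, Chong-Ren Meridians,
#'   Meridians and Collaterals, and Qi-Blood-Fluid).
#' @slot ptRules named list: Preferred Term -> character vector of systems.
#' @slot socRules named list: System Organ Class -> character vector of
#'   systems.
#' @seealso [loadTcmRules()], [mapTerm()], [mapPredictions()]
#' @export
setClass("TcmRuleSet",
  representation(
    systems = "character",
    ptRules = "list",
    socRules = "list"
  )
)

setValidity("TcmRuleSet", function(object) {
  bad <- setdiff(unique(unlist(c(object@ptRules, object@socRules))), object@systems)
  if (length(bad)) {
    return(sprintf(
      "rules target unknown functional system(s): %s", paste(bad, collapse = ", ")
    ))
  }
  TRUE
})

#' Trained MSAT model
#'
#' Bundles the model configuration, the learned encoder/scorer parameters
#' and training provenance (seed, best epoch, validation AUROC) so that a
#' checkpoint can be reloaded and used for deterministic prediction.
#'
#' @slot config list as returned by [msatConfig()].
#' @slot params nested list of numeric parameter arrays (input projections,
#'   per-layer attention/gate/HSP parameters, hub-calibrated scorer).
#' @slot meta list of training provenance (seed, bestEpoch, valAuroc,
#'   degree-standardization statistics).
#' @seealso [initMsatParams()], [trainFold()], [predictPairs()]
#' @export
setClass("MsatModel",
  representation(
    config = "ANY",
    params = "list",
    meta = "list"
  )
)
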