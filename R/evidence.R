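# Six-dimensional edge evidence for CMM-ADR associations: semantic
# similarity, log report count, provenance flag, CMM/ADR degrees, and a
# mechanistic meta-path connectivity score.

#' Cosine similarity of two vectors
#'
#' Returns `u.v / (|u||v|)`, and 0 when either norm is 0 (the convention for
#' missing/degenerate embeddings).
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
cosineSimilarity <- function(u, v) {
  .check(length(u) == length(v), "cosineSimilarity: length mismatch (%d vs %d)",
         length(u), length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Meta-path connectivity between CMM and ADR nodes
#'
#' Counts distinct mechanistic CMM -> Compound -> Target -> ADR chains:
#' the number of (compound, target) pairs such that the CMM-Compound,
#' Compound-Target and Target-ADR edges all exist. Equals the (cmm, adr)
#' entry of the chained biadjacency product A_cm A_mt A_ta.
#'
#' @param graph a [HeteroGraph-class].
#' @return `metapathMatrix()`: integer matrix (rows CMM, columns ADR);
#'   `metapathCount()`: a single count.
#' @export
metapathMatrix <- function(graph) {
  n <- numNodes(graph)
  biadj <- function(rel, nr, nc) {
    em <- graph@edges[[rel]]
    m <- matrix(0, nr, nc)
    if (nrow(em)) m[em] <- 1
    m
  }
  acm <- biadj("CMM-Compound", n["CMM"], n["Compound"])
  amt <- biadj("Compound-Target", n["Compound"], n["Target"])
  ata <- biadj("Target-ADR", n["Target"], n["ADR"])
  mp <- acm %*% amt %*% ata
  dimnames(mp) <- list(graph@nodeIds$CMM, graph@nodeIds$ADR)
  mp
}

#' @rdname metapathMatrix
#' @param cmmId,adrId node ids.
#' @export
metapathCount <- function(graph, cmmId, adrId) {
  ci <- match(cmmId, graph@nodeIds$CMM)
  ai <- match(adrId, graph@nodeIds$ADR)
  .check(!is.na(ci), "unknown CMM node '%s'", cmmId)
  .check(!is.na(ai), "unknown ADR node '%s'", adrId)
  as.integer(metapathMatrix(graph)[ci, ai])
}

# Unscaled evidence features for every stored CMM-ADR edge.
# Count-like features are log1p-transformed here; min-max scaling to [0,1]
# is the scaler's job. Degrees are all-relation incident degrees of the
# (training) graph.
#' Unscaled evidence feature table
#'
#' Computes, for every stored CMM-ADR edge, the raw (pre-scaling) evidence
#' features: cosine similarity of the CMM and ADR node feature vectors,
#' log1p report count, provenance flag (1 = FAERS-derived, 0 =
#' literature-only), log1p all-relation degrees of both endpoints, and the
#' log1p meta-path connectivity score.
#'
#' @param graph a [HeteroGraph-class] with CMM-ADR edge attributes
#'   `report_count` and `provenance`, and feature matrices for CMM and ADR.
#' @return `data.frame` with columns `cmm_id`, `adr_id`, `sem_sim`,
#'   `log_reports`, `provenance_flag`, `cmm_deg`, `adr_deg`, `metapath`.
#' @seealso [fitEvidenceScaler()], [buildEvidenceVectors()]
#' @export
evidenceFeatureTable <- function(graph) {
  em <- graph@edges[["CMM-ADR"]]
  at <- graph@edgeAttrs[["CMM-ADR"]]
  .check(!is.null(at) && all(c("report_count", "provenance") %in% names(at)) ||
           nrow(em) == 0,
         "CMM-ADR edges must carry report_count and provenance attributes")
  featC <- graph@nodeFeatures$CMM
  featA <- graph@nodeFeatures$ADR
  .check(!is.null(featC) && !is.null(featA) || nrow(em) == 0,
         "CMM and ADR node feature matrices are required for sem_sim")
  if (nrow(em) == 0) {
    return(data.frame(
      cmm_id = character(0), adr_id = character(0), sem_sim = numeric(0),
      log_reports = numeric(0), provenance_flag = numeric(0),
      cmm_deg = numeric(0), adr_deg = numeric(0), metapath = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  ci <- em[, 1]
  ai <- em[, 2]
  u <- featC[ci, , drop = FALSE]
  v <- featA[ai, , drop = FALSE]
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  semSim <- ifelse(nu == 0 | nv == 0, 0, rowSums(u * v) / (nu * nv))

  counts <- at$report_count
  prov <- as.numeric(at$provenance == "faers")
  # Literature-only pairs carry no FAERS support: their count feature is 0.
  counts[at$provenance != "faers"] <- 0

  degC <- .degreesOfType(graph, "CMM")
  degA <- .degreesOfType(graph, "ADR")
  mp <- metapathMatrix(graph)

  data.frame(
    cmm_id = graph@nodeIds$CMM[ci],
    adr_id = graph@nodeIds$ADR[ai],
    sem_sim = as.numeric(semSim),
    log_reports = log1p(counts),
    provenance_flag = prov,
    cmm_deg = log1p(degC[ci]),
    adr_deg = log1p(degA[ai]),
    metapath = log1p(mp[cbind(ci, ai)]),
    stringsAsFactors = FALSE
  )
}

#' Fit a min-max evidence scaler on training edges
#'
#' Fits per-feature minima/maxima for the four count-like evidence features
#' (`log_reports`, `cmm_deg`, `adr_deg`, `metapath`) on the training fold's
#' CMM-ADR edges only. `sem_sim` and `provenance_flag` are already bounded
#' and are passed through unscaled.
#'
#' @param rawTable output of [evidenceFeatureTable()], subset to the
#'   training-fold edges.
#' @return an [EvidenceScaler-class].
#' @export
fitEvidenceScaler <- function(rawTable) {
  feats <- c("log_reports", "cmm_deg", "adr_deg", "metapath")
  .check(all(feats %in% names(rawTable)), "rawTable lacks evidence feature columns")
  .check(nrow(rawTable) > 0, "cannot fit a scaler on zero edges")
  methods::new("EvidenceScaler",
    featureNames = feats,
    mins = vapply(feats, function(f) min(rawTable[[f]]), numeric(1)),
    maxs = vapply(feats, function(f) max(rawTable[[f]]), numeric(1)),
    fitted = TRUE
  )
}

setMethod("show", "EvidenceScaler", function(object) {
  cat("EvidenceScaler", if (object@fitted) "(fitted)\n" else "(unfitted)\n")
  if (object@fitted) {
    for (i in seq_along(object@featureNames)) {
      cat(sprintf("  %s: [%.4g, %.4g]\n", object@featureNames[i],
                  object@mins[i], object@maxs[i]))
    }
  }
  invisible(NULL)
})

#' Build scaled six-dimensional evidence vectors
#'
#' Applies a fitted [EvidenceScaler-class] to the raw evidence table of a
#' (training) graph and returns the per-edge six-vectors in canonical
#' feature order: `sem_sim`, `log_reports`, `provenance_flag`, `cmm_deg_n`,
#' `adr_deg_n`, `metapath_n`. Scaled features are clamped to \[0,1\]
#' (held-out edges may exceed the fitted range). Constant features map to 0.
#'
#' @param graph a [HeteroGraph-class]; evidence is computed only from this
#'   graph, so test edges removed via [removePairEdges()] cannot leak in.
#' @param scaler a fitted [EvidenceScaler-class].
#' @return `data.frame` with `cmm_id`, `adr_id` and the six feature columns.
#' @export
buildEvidenceVectors <- function(graph, scaler) {
  .check(methods::is(scaler, "EvidenceScaler") && scaler@fitted,
         "scaler must be a fitted EvidenceScaler")
  raw <- evidenceFeatureTable(graph)
  scale1 <- function(x, f) {
    i <- match(f, scaler@featureNames)
    lo <- scaler@mins[i]
    hi <- scaler@maxs[i]
    if (hi <= lo) return(rep(0, length(x)))
    pmin(pmax((x - lo) / (hi - lo), 0), 1)
  }
  data.frame(
    cmm_id = raw$cmm_id, adr_id = raw$adr_id,
    sem_sim = raw$sem_sim,
    log_reports = scale1(raw$log_reports, "log_reports"),
    provenance_flag = raw$provenance_flag,
    cmm_deg_n = scale1(raw$cmm_deg, "cmm_deg"),
    adr_deg_n = scale1(raw$adr_deg, "adr_deg"),
    metapath_n = scale1(raw$metapath, "metapath"),
    stringsAsFactors = FALSE
  )
}

#' Persist / restore an evidence scaler as JSON
#'
#' @param scaler a fitted [EvidenceScaler-class].
#' @param path JSON file path.
#' @export
saveScaler <- function(scaler, path) {
  jsonlite::write_json(
    list(
      featureNames = scaler@featureNames,
      mins = as.list(stats::setNames(scaler@mins, scaler@featureNames)),
      maxs = as.list(stats::setNames(scaler@maxs, scaler@featureNames))
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname saveScaler
#' @export
loadScaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("EvidenceScaler",
    featureNames = x$featureNames,
    mins = unlist(x$mins)[x$featureNames],
    maxs = unlist(x$maxs)[x$featureNames],
    fitted = TRUE
  )
}
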