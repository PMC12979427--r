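# Multi-scale attention encoder: type-specific input projection, the
# evidence-semantic adaptive gate producing per-head attention biases,
# biased multi-head attention over the bidirected heterogeneous graph, the
# hierarchical expand-and-compress (HSP) transform, and residual + layer
# normalization, stacked L times.

# ---- graph preparation ------------------------------------------------------

# Materialize the directed message-passing graph: canonical edges plus their
# reverses, with global node indices, a directed relation id, and (for
# CMM-ADR edges in either direction) the row of the evidence table carrying
# the shared 6-dimensional evidence vector.
.prepareEncoderGraph <- function(graph, evidenceTable = NULL) {
  nn <- numNodes(graph)
  offsets <- c(0L, cumsum(nn))[seq_along(nn)]
  names(offsets) <- names(nn)
  relNames <- .directedRelationNames()

  src <- integer(0); dst <- integer(0); relId <- integer(0); evidRow <- integer(0)
  for (i in seq_along(.RELATIONS)) {
    rel <- names(.RELATIONS)[i]
    em <- graph@edges[[rel]]
    if (nrow(em) == 0) next
    st <- .RELATIONS[[rel]]
    sG <- offsets[[st[1]]] + em[, 1]
    dG <- offsets[[st[2]]] + em[, 2]
    ev <- rep(NA_integer_, nrow(em))
    if (rel == "CMM-ADR") {
      .check(!is.null(evidenceTable),
             "evidence vectors are required for CMM-ADR edges")
      key <- paste(graph@nodeIds$CMM[em[, 1]], graph@nodeIds$ADR[em[, 2]], sep = "\r")
      ev <- match(key, paste(evidenceTable$cmm_id, evidenceTable$adr_id, sep = "\r"))
      .check(!anyNA(ev), "evidence table lacks rows for some CMM-ADR edges")
    }
    # canonical direction
    src <- c(src, sG); dst <- c(dst, dG)
    relId <- c(relId, rep(i, nrow(em))); evidRow <- c(evidRow, ev)
    # reverse direction (self-relations still add the transposed edges)
    src <- c(src, dG); dst <- c(dst, sG)
    relId <- c(relId, rep(i + length(.RELATIONS), nrow(em))); evidRow <- c(evidRow, ev)
  }

  evFeats <- c("sem_sim", "log_reports", "provenance_flag",
               "cmm_deg_n", "adr_deg_n", "metapath_n")
  E6 <- if (!is.null(evidenceTable) && nrow(evidenceTable) > 0) {
    as.matrix(evidenceTable[, evFeats, drop = FALSE])
  } else {
    matrix(numeric(0), 0, 6, dimnames = list(NULL, evFeats))
  }

  uDst <- sort(unique(dst))
  uSrc <- sort(unique(src))
  grpDst <- match(dst, uDst)
  list(
    nTotal = sum(nn), offsets = offsets, relNames = relNames,
    src = src, dst = dst, relId = relId, evidRow = evidRow,
    isEvid = !is.na(evidRow),
    E6 = E6, nEdges = length(src),
    uDst = uDst, grpDst = grpDst, splitDst = split(seq_along(dst), grpDst),
    uSrc = uSrc, grpSrc = match(src, uSrc)
  )
}

# Stack the per-type embedding matrices into one (nTotal x dh) matrix in the
# canonical type order.
.stackEmbeddings <- function(embList) {
  do.call(rbind, embList[.NODE_TYPES])
}

.splitEmbeddings <- function(Z, graph) {
  nn <- numNodes(graph)
  offsets <- c(0L, cumsum(nn))
  out <- lapply(seq_along(nn), function(i) {
    Z[(offsets[i] + 1):offsets[i + 1], , drop = FALSE]
  })
  names(out) <- names(nn)
  out
}

# ---- exported operations ----------------------------------------------------

#' Project per-type input features to the hidden width
#'
#' Applies the type-specific linear projection to each node type's feature
#' matrix, yielding embeddings of width `heads * headDim`.
#'
#' @param features named list of per-type numeric matrices (any width).
#' @param config an [msatConfig()].
#' @param params parameter list from [initMsatParams()].
#' @return named list of projected matrices (width `config$hidden`).
#' @export
projectInputs <- function(features, config, params) {
  out <- vector("list", length(.NODE_TYPES))
  names(out) <- .NODE_TYPES
  for (ty in .NODE_TYPES) {
    X <- features[[ty]]
    .check(!is.null(X), "missing feature matrix for node type %s", ty)
    p <- params$proj[[ty]]
    Z <- X %*% t(p$W)
    if (!is.null(p$b)) Z <- sweep(Z, 2, p$b, "+")
    out[[ty]] <- Z
  }
  out
}

#' Evidence-semantic adaptive gate
#'
#' Converts a 6-dimensional edge evidence vector into one attention-logit
#' bias per head: `beta = g * MLP(e) + (1 - g) * Ws e`, where
#' `g = sigmoid(theta)` is a learnable scalar gate interpolating between a
#' non-linear branch (one hidden ReLU layer) that extracts risk patterns
#' from reporting evidence and a linear shortcut that preserves the raw
#' statistical signal.
#'
#' @param e evidence vector of length 6, or an (n x 6) matrix.
#' @param layerParams one element of `params$layers`.
#' @return bias vector of length `heads` (or an n x heads matrix).
#' @export
esaGateBias <- function(e, layerParams) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  gp <- layerParams$gate
  .check(ncol(e) == ncol(gp$Ws), "evidence vector must have length %d", ncol(gp$Ws))
  fw <- .gateForward(e, gp)
  if (nrow(e) == 1) drop(fw$beta) else fw$beta
}

.gateForward <- function(e, gp) {
  a <- e %*% t(gp$Wg1)
  a <- sweep(a, 2, gp$bg1, "+")
  h <- .relu(a)
  mlpOut <- sweep(h %*% t(gp$Wg2), 2, gp$bg2, "+")
  lin <- e %*% t(gp$Ws)
  g <- .sigmoid(gp$theta)
  list(beta = g * mlpOut + (1 - g) * lin,
       a = a, h = h, mlpOut = mlpOut, lin = lin, g = g, e = e)
}

#' Bias-modulated multi-head attention over an edge list
#'
#' For each destination node and head, attention weights over its incoming
#' edges are `softmax(Q_i . K_j / sqrt(headDim) + beta_ij)` and the message
#' is the weight-sum of value vectors. Nodes with no incoming edge receive
#' the zero message.
#'
#' @param Q,K,V node-level query/key/value matrices (n x hidden).
#' @param src,dst integer edge endpoint vectors (1-based node rows).
#' @param bias per-edge per-head bias matrix (edges x heads).
#' @param config an [msatConfig()].
#' @return list with `messages` (n x hidden) and `alpha` (edges x heads).
#' @export
biasedAttention <- function(Q, K, V, src, dst, bias, config) {
  n <- nrow(Q)
  uDst <- sort(unique(dst))
  grpDst <- match(dst, uDst)
  prep <- list(uDst = uDst, grpDst = grpDst,
               splitDst = split(seq_along(dst), grpDst))
  att <- .attentionForward(Q, K, V, src, dst, bias, prep, config,
                           dropMask = NULL, n = n)
  list(messages = att$M, alpha = att$alpha)
}

# Core attention forward. dropMask (edges x heads) multiplies the weights
# when training; NULL in evaluation mode.
.attentionForward <- function(Q, K, V, src, dst, bias, prep, config, dropMask, n) {
  H <- config$heads
  d <- config$headDim
  prod <- Q[dst, , drop = FALSE] * K[src, , drop = FALSE]
  # per-head sum over the head's column block
  headOf <- rep(seq_len(H), each = d)
  logits <- t(rowsum(t(prod), headOf)) / sqrt(d) + bias
  dimnames(logits) <- NULL
  # per-destination-group max for a numerically stable softmax
  gmax <- matrix(0, length(prep$uDst), H)
  for (h in seq_len(H)) {
    gmax[, h] <- vapply(prep$splitDst, function(ix) max(logits[ix, h]), numeric(1))
  }
  ex <- exp(logits - gmax[prep$grpDst, , drop = FALSE])
  denom <- rowsum(ex, prep$grpDst)
  alpha <- ex / denom[prep$grpDst, , drop = FALSE]
  dimnames(alpha) <- NULL
  alphaD <- if (is.null(dropMask)) alpha else alpha * dropMask
  M <- matrix(0, n, H * d)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * d + 1):(h * d)
    contrib <- alphaD[, h] * V[src, cols, drop = FALSE]
    agg <- rowsum(contrib, prep$grpDst)
    M[prep$uDst, cols] <- M[prep$uDst, cols] + agg
  }
  list(M = M, alpha = alpha, alphaD = alphaD, logits = logits)
}

#' Hierarchical signal propagation transform
#'
#' Expand-and-compress feed-forward block applied to the aggregated
#' message: widths `hidden -> 2*hidden -> 3*hidden -> hidden` with ReLU
#' between the linear maps, emulating signal amplification across
#' biological scales before projecting back for the residual connection.
#'
#' @param m message vector of length `hidden`, or an (n x hidden) matrix.
#' @param layerParams one element of `params$layers`.
#' @return transformed vector/matrix of the same width.
#' @export
hspTransform <- function(m, layerParams) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, nrow = 1)
  .check(ncol(m) == ncol(layerParams$W1),
         "hspTransform: input width %d != hidden width %d",
         ncol(m), ncol(layerParams$W1))
  out <- .hspForward(m, layerParams)$u
  if (vec) drop(out) else out
}

.hspForward <- function(m, lp) {
  a1 <- m %*% t(lp$W1)
  r1 <- .relu(a1)
  a2 <- r1 %*% t(lp$W2)
  r2 <- .relu(a2)
  u <- r2 %*% t(lp$W3)
  list(u = u, a1 = a1, r1 = r1, a2 = a2, r2 = r2)
}

.layerNormForward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  invSd <- 1 / sqrt(v + eps)
  xhat <- xc * invSd
  out <- sweep(xhat * rep(1, nrow(x)) %o% gamma, 2, beta, "+")
  list(out = out, xhat = xhat, invSd = invSd)
}

# Assemble the per-edge bias matrix for one layer: evidence-gated bias on
# CMM-ADR edges (both directions share the edge's evidence vector), a
# learnable per-relation per-head bias elsewhere.
.layerBias <- function(lp, prep) {
  bias <- lp$relBias[prep$relId, , drop = FALSE]
  gateCache <- NULL
  if (any(prep$isEvid)) {
    gateCache <- .gateForward(prep$E6, lp$gate)
    bias[prep$isEvid, ] <- gateCache$beta[prep$evidRow[prep$isEvid], , drop = FALSE]
  }
  list(bias = bias, gateCache = gateCache)
}

# One full layer forward with cache (used by both the exported layer op and
# the training backward pass).
.layerForward <- function(Z, lp, prep, config, training = FALSE) {
  n <- nrow(Z)
  Q <- Z %*% lp$Wq
  K <- Z %*% lp$Wk
  V <- Z %*% lp$Wv
  lb <- .layerBias(lp, prep)
  dropMask <- NULL
  hspMask <- NULL
  if (training && config$dropout > 0) {
    p <- config$dropout
    dropMask <- matrix(
      stats::rbinom(prep$nEdges * config$heads, 1, 1 - p) / (1 - p),
      prep$nEdges, config$heads
    )
    hspMask <- matrix(
      stats::rbinom(n * config$hidden, 1, 1 - p) / (1 - p),
      n, config$hidden
    )
  }
  att <- .attentionForward(Q, K, V, prep$src, prep$dst, lb$bias, prep, config,
                           dropMask, n)
  hsp <- .hspForward(att$M, lp)
  u <- if (is.null(hspMask)) hsp$u else hsp$u * hspMask
  res <- u + Z
  ln <- .layerNormForward(res, lp$ln$gamma, lp$ln$beta)
  list(
    out = ln$out,
    cache = list(
      Z = Z, Q = Q, K = K, V = V, bias = lb$bias, gateCache = lb$gateCache,
      att = att, hsp = hsp, dropMask = dropMask, hspMask = hspMask,
      ln = ln
    )
  )
}

#' Apply one multi-scale attention layer
#'
#' Computes `LayerNorm(HSP(attention(h)) + h)` over the bidirected
#' heterogeneous graph, with evidence-gated attention biases on CMM-ADR
#' edges and learned per-relation biases elsewhere.
#'
#' @param embeddings named list of per-type embedding matrices of width
#'   `config$hidden` (as from [projectInputs()]).
#' @param graph a [HeteroGraph-class].
#' @param evidenceTable scaled evidence table from [buildEvidenceVectors()]
#'   covering every stored CMM-ADR edge.
#' @param layerParams one element of `params$layers`.
#' @param config an [msatConfig()].
#' @return named list of updated per-type embedding matrices.
#' @export
msatLayer <- function(embeddings, graph, evidenceTable, layerParams, config) {
  Z <- .stackEmbeddings(embeddings)
  .check(ncol(Z) == config$hidden, "embedding width %d != hidden width %d",
         ncol(Z), config$hidden)
  prep <- .prepareEncoderGraph(graph, evidenceTable)
  out <- .layerForward(Z, layerParams, prep, config, training = FALSE)$out
  .splitEmbeddings(out, graph)
}

#' Encode a heterogeneous graph
#'
#' Full encoder: type-specific input projection followed by `config$layers`
#' stacked attention layers. Deterministic in evaluation mode (dropout off).
#'
#' @param graph a [HeteroGraph-class] with feature matrices for all types.
#' @param evidenceTable scaled evidence table covering every stored CMM-ADR
#'   edge (see [buildEvidenceVectors()]).
#' @param config an [msatConfig()].
#' @param params parameter list from [initMsatParams()].
#' @return named list of final per-type embedding matrices.
#' @export
encodeGraph <- function(graph, evidenceTable, config, params) {
  prep <- .prepareEncoderGraph(graph, evidenceTable)
  Z <- .stackEmbeddings(projectInputs(graph@nodeFeatures, config, params))
  for (l in seq_len(config$layers)) {
    Z <- .layerForward(Z, params$layers[[l]], prep, config, training = FALSE)$out
  }
  .splitEmbeddings(Z, graph)
}

# Encoder forward keeping caches for backpropagation.
.encodeForwardCached <- function(graph, prep, config, params, training) {
  X <- graph@nodeFeatures
  emb <- projectInputs(X, config, params)
  Z <- .stackEmbeddings(emb)
  caches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    fw <- .layerForward(Z, params$layers[[l]], prep, config, training)
    caches[[l]] <- fw$cache
    Z <- fw$out
  }
  list(Z = Z, caches = caches, X = X)
}
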