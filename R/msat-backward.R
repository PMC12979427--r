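# Reverse-mode gradients for the encoder + scorer, hand-derived and checked
# against finite differences in the test suite. All functions are internal:
# the exported training surface is trainFold()/predictPairs().

# ---- scorer -----------------------------------------------------------------

.scorerForwardCached <- function(Z, ci, ai, degC, degA, sp) {
  Zc <- Z[ci, , drop = FALSE]
  Za <- Z[ai, , drop = FALSE]
  x <- cbind(Zc, Za, degC, degA)
  hPre <- sweep(x %*% t(sp$Wm1), 2, sp$bm1, "+")
  h <- .relu(hPre)
  sMlp <- drop(h %*% t(sp$wm2)) + sp$bm2
  sBil <- drop(rowSums((Zc %*% sp$WB) * Za))
  sDm <- drop((Zc * Za) %*% sp$r)
  s <- sp$w[1] * sMlp + sp$w[2] * sBil + sp$w[3] * sDm
  list(
    s = s, p = .sigmoid(s),
    Zc = Zc, Za = Za, x = x, hPre = hPre, h = h,
    sMlp = sMlp, sBil = sBil, sDm = sDm
  )
}

# ds: dLoss/ds per pair. Returns scorer grads plus dZ accumulated at the
# encoder output.
.scorerBackward <- function(ds, fw, ci, ai, sp, nTotal) {
  dh <- ncol(fw$Zc)
  g <- list()
  g$w <- c(sum(ds * fw$sMlp), sum(ds * fw$sBil), sum(ds * fw$sDm))

  # MLP branch
  dsMlp <- sp$w[1] * ds
  g$wm2 <- matrix(colSums(fw$h * dsMlp), 1)
  g$bm2 <- sum(dsMlp)
  dhid <- dsMlp %o% drop(sp$wm2)
  dhid <- dhid * (fw$hPre > 0)
  g$Wm1 <- t(dhid) %*% fw$x
  g$bm1 <- colSums(dhid)
  dx <- dhid %*% sp$Wm1
  dZc <- dx[, seq_len(dh), drop = FALSE]
  dZa <- dx[, dh + seq_len(dh), drop = FALSE]

  # bilinear branch
  ds2 <- sp$w[2] * ds
  dZc <- dZc + ds2 * (fw$Za %*% t(sp$WB))
  dZa <- dZa + ds2 * (fw$Zc %*% sp$WB)
  g$WB <- t(fw$Zc * ds2) %*% fw$Za

  # DistMult branch
  ds3 <- sp$w[3] * ds
  rMat <- rep(1, length(ds)) %o% sp$r
  dZc <- dZc + ds3 * (fw$Za * rMat)
  dZa <- dZa + ds3 * (fw$Zc * rMat)
  g$r <- colSums(ds3 * (fw$Zc * fw$Za))

  dZ <- matrix(0, nTotal, dh)
  aggC <- rowsum(dZc, ci)
  dZ[as.integer(rownames(aggC)), ] <- dZ[as.integer(rownames(aggC)), ] + aggC
  aggA <- rowsum(dZa, ai)
  dZ[as.integer(rownames(aggA)), ] <- dZ[as.integer(rownames(aggA)), ] + aggA
  list(grads = g, dZ = dZ)
}

# ---- layer ------------------------------------------------------------------

.layerNormBackward <- function(dOut, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, gamma, "*")
  dres <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$invSd
  list(dres = dres, dgamma = dgamma, dbeta = dbeta)
}

.layerBackward <- function(dOut, cache, lp, prep, config) {
  H <- config$heads
  d <- config$headDim
  n <- nrow(dOut)

  ln <- .layerNormBackward(dOut, cache$ln, lp$ln$gamma)
  dres <- ln$dres
  dU <- if (is.null(cache$hspMask)) dres else dres * cache$hspMask

  # HSP backward
  hsp <- cache$hsp
  dR2 <- dU %*% lp$W3
  dW3 <- t(dU) %*% hsp$r2
  da2 <- dR2 * (hsp$a2 > 0)
  dW2 <- t(da2) %*% hsp$r1
  dR1 <- da2 %*% lp$W2
  da1 <- dR1 * (hsp$a1 > 0)
  dW1 <- t(da1) %*% cache$att$M
  dM <- da1 %*% lp$W1

  # attention backward
  att <- cache$att
  src <- prep$src
  dst <- prep$dst
  E <- prep$nEdges
  dAlphaD <- matrix(0, E, H)
  dQ <- matrix(0, n, H * d)
  dK <- dQ
  dV <- dQ
  for (h in seq_len(H)) {
    cols <- ((h - 1) * d + 1):(h * d)
    dMd <- dM[dst, cols, drop = FALSE]
    Vs <- cache$V[src, cols, drop = FALSE]
    dAlphaD[, h] <- rowSums(dMd * Vs)
    aggV <- rowsum(att$alphaD[, h] * dMd, prep$grpSrc)
    dV[prep$uSrc, cols] <- dV[prep$uSrc, cols] + aggV
  }
  dAlpha <- if (is.null(cache$dropMask)) dAlphaD else dAlphaD * cache$dropMask
  sg <- rowsum(att$alpha * dAlpha, prep$grpDst)
  dLogit <- att$alpha * (dAlpha - sg[prep$grpDst, , drop = FALSE])
  for (h in seq_len(H)) {
    cols <- ((h - 1) * d + 1):(h * d)
    aggQ <- rowsum(dLogit[, h] * cache$K[src, cols, drop = FALSE] / sqrt(d),
                   prep$grpDst)
    dQ[prep$uDst, cols] <- dQ[prep$uDst, cols] + aggQ
    aggK <- rowsum(dLogit[, h] * cache$Q[dst, cols, drop = FALSE] / sqrt(d),
                   prep$grpSrc)
    dK[prep$uSrc, cols] <- dK[prep$uSrc, cols] + aggK
  }

  # bias backward: per-relation biases on mechanistic edges, evidence gate
  # on CMM-ADR edges (both directions accumulate on the shared vector)
  nRel <- nrow(lp$relBias)
  dRelBias <- matrix(0, nRel, ncol(lp$relBias))
  nonEvid <- !prep$isEvid
  if (any(nonEvid)) {
    agg <- rowsum(dLogit[nonEvid, , drop = FALSE], prep$relId[nonEvid])
    dRelBias[as.integer(rownames(agg)), ] <- agg
  }
  gGate <- list(theta = 0, Wg1 = lp$gate$Wg1 * 0, bg1 = lp$gate$bg1 * 0,
                Wg2 = lp$gate$Wg2 * 0, bg2 = lp$gate$bg2 * 0,
                Ws = lp$gate$Ws * 0)
  if (any(prep$isEvid)) {
    gc <- cache$gateCache
    dBeta <- matrix(0, nrow(prep$E6), H)
    agg <- rowsum(dLogit[prep$isEvid, , drop = FALSE],
                  prep$evidRow[prep$isEvid])
    dBeta[as.integer(rownames(agg)), ] <- agg
    g <- gc$g
    dMlpOut <- g * dBeta
    dLin <- (1 - g) * dBeta
    gGate$theta <- sum(dBeta * (gc$mlpOut - gc$lin)) * g * (1 - g)
    gGate$Ws <- t(dLin) %*% gc$e
    gGate$Wg2 <- t(dMlpOut) %*% gc$h
    gGate$bg2 <- colSums(dMlpOut)
    dhg <- dMlpOut %*% lp$gate$Wg2
    dag <- dhg * (gc$a > 0)
    gGate$Wg1 <- t(dag) %*% gc$e
    gGate$bg1 <- colSums(dag)
  }

  Zin <- cache$Z
  dWq <- t(Zin) %*% dQ
  dWk <- t(Zin) %*% dK
  dWv <- t(Zin) %*% dV
  dZ <- dres + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)

  list(
    dZ = dZ,
    grads = list(
      gate = gGate, relBias = dRelBias,
      Wq = dWq, Wk = dWk, Wv = dWv,
      W1 = dW1, W2 = dW2, W3 = dW3,
      ln = list(gamma = ln$dgamma, beta = ln$dbeta)
    )
  )
}

# ---- full loss + gradient ---------------------------------------------------

# Binary cross-entropy over a batch of (pair, label) with full-graph
# encoding. ci/ai are global node rows; degC/degA the standardized degree
# features of the pairs.
.lossAndGrads <- function(params, config, graph, prep, ci, ai, y, degC, degA,
                          training = TRUE) {
  enc <- .encodeForwardCached(graph, prep, config, params, training)
  sfw <- .scorerForwardCached(enc$Z, ci, ai, degC, degA, params$scorer)
  eps <- 1e-12
  p <- pmin(pmax(sfw$p, eps), 1 - eps)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (!is.finite(loss)) {
    stop(sprintf("non-finite training loss (%g); aborting", loss), call. = FALSE)
  }
  ds <- (sfw$p - y) / length(y)
  sb <- .scorerBackward(ds, sfw, ci, ai, params$scorer, prep$nTotal)

  dZ <- sb$dZ
  layerGrads <- vector("list", config$layers)
  for (l in rev(seq_len(config$layers))) {
    lb <- .layerBackward(dZ, enc$caches[[l]], params$layers[[l]], prep, config)
    layerGrads[[l]] <- lb$grads
    dZ <- lb$dZ
  }

  # projection backward over the per-type blocks
  nn <- numNodes(graph)
  offs <- c(0L, cumsum(nn))
  projGrads <- vector("list", length(.NODE_TYPES))
  names(projGrads) <- .NODE_TYPES
  for (i in seq_along(.NODE_TYPES)) {
    ty <- .NODE_TYPES[i]
    rows <- if (nn[i] > 0) (offs[i] + 1):offs[i + 1] else integer(0)
    dZt <- dZ[rows, , drop = FALSE]
    Xt <- enc$X[[ty]]
    projGrads[[ty]] <- list(
      W = t(dZt) %*% Xt,
      b = if (config$projBias) colSums(dZt) else NULL
    )
  }

  list(
    loss = loss, p = sfw$p,
    grads = list(proj = projGrads, layers = layerGrads, scorer = sb$grads)
  )
}
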