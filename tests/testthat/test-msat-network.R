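# Encoder operations: input projection, evidence gate, biased attention,
# expand-and-compress transform, full layers, and gradient correctness.

test_that("projectInputs maps every type to the hidden width", {
  cfg <- tinyModelConfig()
  dh <- cfg$hidden
  feats <- list(CMM = matrix(rnorm(10), 5, 2), Compound = matrix(rnorm(6), 3, 2),
                Target = matrix(rnorm(8), 4, 2), ADR = matrix(rnorm(4), 2, 2))
  params <- initMsatParams(cfg, c(CMM = 2L, Compound = 2L, Target = 2L, ADR = 2L),
                           seed = 2)
  out <- projectInputs(feats, cfg, params)
  expect_equal(vapply(out, ncol, 0L),
               c(CMM = dh, Compound = dh, Target = dh, ADR = dh))
  expect_equal(nrow(out$CMM), 5L)

  # identity weights leave a width-dh input unchanged
  idFeats <- list(CMM = matrix(rnorm(2 * dh), 2, dh))
  p2 <- params
  p2$proj$CMM$W <- diag(dh)
  p2$proj$CMM$b <- numeric(dh)
  feats2 <- feats
  feats2$CMM <- idFeats$CMM
  p2$proj$Compound$W <- matrix(0, dh, 2)
  out2 <- projectInputs(feats2, cfg, p2)
  expect_equal(out2$CMM, idFeats$CMM)
  # zero features with zero bias give zero embeddings
  feats2$Compound <- matrix(0, 3, 2)
  expect_true(all(projectInputs(feats2, cfg, p2)$Compound == 0))

  expect_error(projectInputs(feats[-1], cfg, params), "missing feature")
})

test_that("esaGateBias interpolates the MLP and linear branches via the gate", {
  cfg <- msatConfig(heads = 1L, headDim = 2L, layers = 1L, dropout = 0,
                    gateHidden = 1L)
  lp <- initMsatParams(cfg, c(CMM = 2L, Compound = 2L, Target = 2L, ADR = 2L),
                       seed = 1)$layers[[1]]
  e <- c(0.5, 1, 0, 0.2, 0.3, 0.1)

  # all-zero weights give a zero bias
  lp0 <- lp
  lp0$gate[c("Wg1", "Wg2", "Ws")] <- lapply(lp$gate[c("Wg1", "Wg2", "Ws")],
                                            function(m) m * 0)
  expect_equal(esaGateBias(e, lp0), 0)

  # scalar toy: MLP(e) = 2, Ws e = 4, theta = 0 (g = 0.5) -> bias 3
  lpToy <- lp
  lpToy$gate$theta <- 0
  lpToy$gate$Wg1 <- matrix(c(1, 0, 0, 0, 0, 0), 1, 6) # hidden = e[1] = 0.5
  lpToy$gate$bg1 <- 0
  lpToy$gate$Wg2 <- matrix(4, 1, 1) # mlp out = 4 * 0.5 = 2
  lpToy$gate$bg2 <- 0
  lpToy$gate$Ws <- matrix(c(8, 0, 0, 0, 0, 0), 1, 6) # lin = 8 * 0.5 = 4
  expect_equal(esaGateBias(e, lpToy), 0.5 * 2 + 0.5 * 4)

  # gate saturation: theta = 30 gives the pure MLP branch to float precision
  lpSat <- lpToy
  lpSat$gate$theta <- 30
  expect_equal(esaGateBias(e, lpSat), 2, tolerance = 1e-10)
  # theta = -30 gives the pure linear branch
  lpSat$gate$theta <- -30
  expect_equal(esaGateBias(e, lpSat), 4, tolerance = 1e-10)

  # exact convex combination at intermediate theta (scalar oracle)
  lpMid <- lpToy
  lpMid$gate$theta <- 0.7
  g <- 1 / (1 + exp(-0.7))
  expect_equal(esaGateBias(e, lpMid), g * 2 + (1 - g) * 4)

  expect_error(esaGateBias(c(1, 2), lp), "length")
})

test_that("biasedAttention normalizes per head and matches softmax arithmetic", {
  cfg <- msatConfig(heads = 2L, headDim = 2L, layers = 1L, dropout = 0)
  n <- 3L
  dh <- cfg$hidden
  # equal logits: zero Q/K makes all logits 0
  Q <- matrix(0, n, dh)
  K <- matrix(0, n, dh)
  V <- matrix(rnorm(n * dh), n, dh)
  src <- c(1L, 2L)
  dst <- c(3L, 3L)
  res <- biasedAttention(Q, K, V, src, dst, matrix(0, 2, 2), cfg)
  expect_equal(res$alpha, matrix(0.5, 2, 2))
  expect_equal(res$messages[3, ], 0.5 * V[1, ] + 0.5 * V[2, ])
  # nodes without incoming edges get the zero message
  expect_equal(res$messages[1, ], rep(0, dh))

  # bias ln(3) on one head tilts its weights to 0.75/0.25
  bias <- matrix(0, 2, 2)
  bias[1, 1] <- log(3)
  res2 <- biasedAttention(Q, K, V, src, dst, bias, cfg)
  expect_equal(res2$alpha[, 1], c(0.75, 0.25))
  expect_equal(res2$alpha[, 2], c(0.5, 0.5))

  # weights sum to one per destination and head on a random instance
  set.seed(8)
  Qr <- matrix(rnorm(n * dh), n, dh)
  Kr <- matrix(rnorm(n * dh), n, dh)
  srcR <- c(1L, 2L, 3L, 1L, 2L)
  dstR <- c(2L, 2L, 2L, 3L, 3L)
  res3 <- biasedAttention(Qr, Kr, V, srcR, dstR, matrix(rnorm(10), 5, 2), cfg)
  sums <- rowsum(res3$alpha, dstR)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("hspTransform traverses the expand-and-compress widths", {
  # default configuration: 576 -> 1152 -> 1728 -> 576
  dflt <- msatConfig()
  p <- initMsatParams(dflt, c(CMM = 4L, Compound = 4L, Target = 4L, ADR = 4L),
                      seed = 1)
  expect_equal(dflt$hidden, 576L)
  expect_equal(dim(p$layers[[1]]$W1), c(1152L, 576L))
  expect_equal(dim(p$layers[[1]]$W2), c(1728L, 1152L))
  expect_equal(dim(p$layers[[1]]$W3), c(576L, 1728L))
  m <- rnorm(576)
  expect_length(hspTransform(m, p$layers[[1]]), 576L)

  # toy width-2 instance against direct three-matrix evaluation
  cfg <- msatConfig(heads = 1L, headDim = 2L, layers = 1L)
  lp <- initMsatParams(cfg, c(CMM = 2L, Compound = 2L, Target = 2L, ADR = 2L),
                       seed = 3)$layers[[1]]
  lp$W1 <- matrix(c(1, -1, 0.5, 2, 0, 1, -2, 0.3), 4, 2)
  lp$W2 <- matrix(rnorm(24), 6, 4)
  lp$W3 <- matrix(rnorm(12), 2, 6)
  x <- c(0.3, -0.7)
  want <- drop(lp$W3 %*% pmax(lp$W2 %*% pmax(lp$W1 %*% x, 0), 0))
  expect_equal(hspTransform(x, lp), want)

  # all-zero weights give the zero output
  lp0 <- lp
  lp0$W1 <- lp$W1 * 0
  expect_equal(hspTransform(x, lp0), c(0, 0))
  expect_error(hspTransform(c(1, 2, 3), lp), "width")
})

test_that("msatLayer is a normalized residual update with conserved shape", {
  g <- tinyGraph()
  cfg <- tinyModelConfig()
  dims <- vapply(g@nodeFeatures, ncol, 0L)
  params <- initMsatParams(cfg, dims, seed = 4)
  ev <- tinyEvidence(g)
  emb <- projectInputs(g@nodeFeatures, cfg, params)
  out <- msatLayer(emb, g, ev, params$layers[[1]], cfg)
  expect_equal(vapply(out, dim, integer(2)), vapply(emb, dim, integer(2)))

  # zero attention values and zero HSP weights reduce to LayerNorm(h)
  lp0 <- params$layers[[1]]
  lp0$Wv <- lp0$Wv * 0
  lp0$W3 <- lp0$W3 * 0
  out0 <- msatLayer(emb, g, ev, lp0, cfg)
  Z <- msat:::.stackEmbeddings(emb)
  want <- msat:::.layerNormForward(Z, lp0$ln$gamma, lp0$ln$beta)$out
  expect_equal(msat:::.stackEmbeddings(out0), want)

  # evaluation mode is deterministic
  out2 <- msatLayer(emb, g, ev, params$layers[[1]], cfg)
  expect_identical(out, out2)
})

test_that("encodeGraph composes projection and layers deterministically", {
  g <- tinyGraph()
  cfg1 <- tinyModelConfig(layers = 1L)
  dims <- vapply(g@nodeFeatures, ncol, 0L)
  params <- initMsatParams(cfg1, dims, seed = 5)
  ev <- tinyEvidence(g)
  # L = 1 equals projection followed by one layer
  enc <- encodeGraph(g, ev, cfg1, params)
  manual <- msatLayer(projectInputs(g@nodeFeatures, cfg1, params), g, ev,
                      params$layers[[1]], cfg1)
  expect_equal(enc, manual)
  expect_identical(enc, encodeGraph(g, ev, cfg1, params))

  # removing a CMM-ADR edge changes the embeddings
  g2 <- removePairEdges(g, data.frame(cmm_id = "cmm1", adr_id = "adr1"))
  enc2 <- encodeGraph(g2, tinyEvidence(g2), cfg1, params)
  expect_gt(max(abs(enc2$CMM - enc$CMM)), 1e-8)
})

test_that("encoder is equivariant to node relabeling", {
  dat <- smallSynth(seed = 3)
  g <- dat$graph
  cfg <- tinyModelConfig(layers = 1L)
  dims <- vapply(g@nodeFeatures, ncol, 0L)
  params <- initMsatParams(cfg, dims, seed = 6)
  ev <- tinyEvidence(g)
  enc <- encodeGraph(g, ev, cfg, params)

  # permute the CMM nodes: rebuild the graph with reordered ids/features
  set.seed(10)
  perm <- sample(length(g@nodeIds$CMM))
  nodes2 <- g@nodeIds
  nodes2$CMM <- g@nodeIds$CMM[perm]
  edges2 <- lapply(names(msat:::.RELATIONS), function(rel) edgeTable(g, rel))
  names(edges2) <- names(msat:::.RELATIONS)
  feats2 <- g@nodeFeatures
  feats2$CMM <- feats2$CMM[perm, , drop = FALSE]
  g2 <- heteroGraph(nodes = nodes2,
                    edges = edges2[vapply(edges2, nrow, 0L) > 0],
                    features = feats2)
  enc2 <- encodeGraph(g2, ev, cfg, params)
  expect_equal(enc2$CMM, enc$CMM[perm, , drop = FALSE], tolerance = 1e-10)
  expect_equal(enc2$ADR, enc$ADR, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  dat <- generateSyntheticData(synthConfig(
    nCmm = 6L, nCompound = 8L, nTarget = 10L, nAdr = 6L, featureDim = 4L,
    nLatentClusters = 3L,
    densities = list(cmmCompound = 0.3, compoundTarget = 0.3, cmmTarget = 0.1,
                     targetTarget = 0.1, targetAdr = 0.3), seed = 5
  ))
  cfg <- msatConfig(heads = 2L, headDim = 3L, layers = 2L, dropout = 0,
                    gateHidden = 4L, scorerHidden = 5L)
  ev <- buildEvidenceVectors(dat$graph,
                             fitEvidenceScaler(evidenceFeatureTable(dat$graph)))
  dims <- vapply(dat$graph@nodeFeatures, ncol, 0L)
  params <- initMsatParams(cfg, dims, seed = 3)
  prep <- msat:::.prepareEncoderGraph(dat$graph, ev)
  degF <- msat:::.degreeFeatures(dat$graph)
  pairs <- rbind(
    data.frame(cmm_id = dat$pairs$cmm_id, adr_id = dat$pairs$adr_id, label = 1),
    data.frame(cmm_id = "cmm001", adr_id = "adr003", label = 0)
  )
  idx <- msat:::.pairIndex(dat$graph, pairs, degF)
  y <- pairs$label
  lossAt <- function(p) {
    msat:::.lossAndGrads(p, cfg, dat$graph, prep, idx$ci, idx$ai, y,
                         idx$degC, idx$degA, training = FALSE)$loss
  }
  fg <- msat:::.lossAndGrads(params, cfg, dat$graph, prep, idx$ci, idx$ai, y,
                             idx$degC, idx$degA, training = FALSE)
  flatP <- msat:::.flattenParams(params)
  flatG <- msat:::.flattenParams(fg$grads)
  eps <- 1e-6
  set.seed(99)
  for (nm in names(flatP)) {
    for (j in sample(seq_along(flatP[[nm]]), min(2, length(flatP[[nm]])))) {
      up <- flatP; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- flatP; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (lossAt(msat:::.unflattenParams(up, params)) -
                lossAt(msat:::.unflattenParams(dn, params))) / (2 * eps)
      expect_equal(flatG[[nm]][j], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, j))
    }
  }
})
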