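# Per-fold optimization: binary cross-entropy on sampled pairs, AdamW with
# gradient clipping, plateau learning-rate schedule, early stopping on
# validation AUROC, and best-checkpoint tracking.

#' Training configuration
#'
#' Defaults follow the reference protocol: AdamW at learning rate 4e-4 with
#' weight decay 1e-5, mini-batches of 512 pairs, up to 1000 epochs with
#' early-stopping patience 100 on validation AUROC, gradient clipping at
#' global norm 1.0, and a reduce-on-plateau schedule (factor 0.6,
#' patience 15).
#'
#' @param learningRate initial AdamW learning rate.
#' @param weightDecay decoupled weight decay.
#' @param batchSize pairs per optimization step.
#' @param maxEpochs maximum training epochs.
#' @param earlyStopPatience epochs without validation-AUROC improvement
#'   before stopping.
#' @param clipNorm maximum global gradient norm.
#' @param schedulerFactor multiplicative learning-rate decay on plateau.
#' @param schedulerPatience non-improving epochs before a decay step.
#' @param seed RNG seed controlling initialization, batching and dropout.
#' @return list of class `msatTrainConfig`.
#' @export
trainConfig <- function(learningRate = 4e-4, weightDecay = 1e-5,
                        batchSize = 512L, maxEpochs = 1000L,
                        earlyStopPatience = 100L, clipNorm = 1.0,
                        schedulerFactor = 0.6, schedulerPatience = 15L,
                        seed = 42L) {
  .check(learningRate > 0 && weightDecay >= 0 && batchSize >= 1 &&
           maxEpochs >= 1 && clipNorm > 0 && schedulerFactor > 0 &&
           schedulerFactor < 1, "invalid training configuration")
  cfg <- list(
    learningRate = learningRate, weightDecay = weightDecay,
    batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
    earlyStopPatience = as.integer(earlyStopPatience), clipNorm = clipNorm,
    schedulerFactor = schedulerFactor,
    schedulerPatience = as.integer(schedulerPatience), seed = as.integer(seed)
  )
  class(cfg) <- "msatTrainConfig"
  cfg
}

.adamwStep <- function(params, grads, m, v, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(params)) return(list(params = NULL, m = NULL, v = NULL))
  if (is.list(params)) {
    for (nm in names(params)) {
      res <- .adamwStep(params[[nm]], grads[[nm]], m[[nm]], v[[nm]],
                        lr, wd, t, beta1, beta2, eps)
      params[[nm]] <- res$params
      m[[nm]] <- res$m
      v[[nm]] <- res$v
    }
    return(list(params = params, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  params <- params - lr * (mh / (sqrt(vh) + eps) + wd * params)
  list(params = params, m = m, v = v)
}

.clipGrads <- function(grads, clipNorm) {
  gn <- sqrt(.sumParams(function(x) sum(x^2), grads))
  if (is.finite(gn) && gn > clipNorm) {
    grads <- .mapParams(function(x) x * (clipNorm / gn), grads)
    gn <- clipNorm
  }
  list(grads = grads, norm = gn)
}

# Standardized log1p all-relation degree features of the training graph.
.degreeFeatures <- function(graph) {
  mk <- function(type) {
    ld <- log1p(.degreesOfType(graph, type))
    mu <- mean(ld)
    sd <- stats::sd(ld)
    if (!is.finite(sd) || sd == 0) sd <- 1
    list(z = (ld - mu) / sd, mu = mu, sd = sd)
  }
  list(CMM = mk("CMM"), ADR = mk("ADR"))
}

# Map id pairs to global encoder rows + degree features.
.pairIndex <- function(graph, pairs, degFeat) {
  nn <- numNodes(graph)
  offsets <- c(0L, cumsum(nn))
  names(offsets) <- c(names(nn), "end")
  cLoc <- match(as.character(pairs$cmm_id), graph@nodeIds$CMM)
  aLoc <- match(as.character(pairs$adr_id), graph@nodeIds$ADR)
  .check(!anyNA(cLoc) && !anyNA(aLoc), "pairs reference unknown node id(s)")
  list(
    ci = offsets[["CMM"]] + cLoc,
    ai = offsets[["ADR"]] + aLoc,
    degC = degFeat$CMM$z[cLoc],
    degA = degFeat$ADR$z[aLoc]
  )
}

.predictIdx <- function(params, config, graph, prep, idx) {
  enc <- .encodeForwardCached(graph, prep, config, params, training = FALSE)
  fw <- .scorerForwardCached(enc$Z, idx$ci, idx$ai, idx$degC, idx$degA,
                             params$scorer)
  fw$p
}

#' Train one cross-validation fold
#'
#' Optimizes the encoder + scorer on the fold's training pairs with binary
#' cross-entropy. The graph must already have the held-out test positives
#' removed in both directions (see [removePairEdges()]); the evidence table
#' must cover exactly the remaining CMM-ADR edges. Per epoch the validation
#' AUROC is evaluated in deterministic evaluation mode; the best-AUROC
#' parameter snapshot is returned. Training stops at `maxEpochs` or after
#' `earlyStopPatience` epochs without improvement; the learning rate decays
#' by `schedulerFactor` after `schedulerPatience` non-improving epochs.
#'
#' @param graph the fold's training [HeteroGraph-class] (test edges removed,
#'   feature matrices for all node types).
#' @param evidenceTable scaled evidence table from [buildEvidenceVectors()].
#' @param split list with elements `train` and `val`, each a `data.frame`
#'   with columns `cmm_id`, `adr_id`, `label` (0/1); negatives are expected
#'   to be pre-sampled and cached (see [sampleNegatives()]).
#' @param modelConfig an [msatConfig()].
#' @param config an [trainConfig()].
#' @return list with `model` (a [MsatModel-class] at the best validation
#'   epoch) and `log` (`data.frame` of per-epoch train loss, validation
#'   AUROC and learning rate).
#' @seealso [predictPairs()], [runCv()]
#' @export
trainFold <- function(graph, evidenceTable, split, modelConfig,
                      config = trainConfig()) {
  .check(nrow(split$train) > 0 && nrow(split$val) > 0,
         "train and validation splits must be non-empty")
  .check(length(unique(split$val$label)) == 2,
         "validation split must contain both classes")
  for (ty in .NODE_TYPES) {
    .check(!is.null(graph@nodeFeatures[[ty]]),
           "node type %s lacks a feature matrix", ty)
  }
  set.seed(config$seed)
  prep <- .prepareEncoderGraph(graph, evidenceTable)
  featureDims <- vapply(graph@nodeFeatures, ncol, integer(1))
  params <- initMsatParams(modelConfig, featureDims, seed = config$seed)

  degFeat <- .degreeFeatures(graph)
  trIdx <- .pairIndex(graph, split$train, degFeat)
  vaIdx <- .pairIndex(graph, split$val, degFeat)
  yTr <- split$train$label
  nTr <- length(yTr)

  adamM <- .zerosLike(params)
  adamV <- .zerosLike(params)
  lr <- config$learningRate
  stepT <- 0L
  best <- -Inf
  bestParams <- params
  bestEpoch <- 0L
  badEpochs <- 0L
  schedBad <- 0L
  logRows <- vector("list", config$maxEpochs)

  for (epoch in seq_len(config$maxEpochs)) {
    perm <- sample.int(nTr)
    starts <- seq(1, nTr, by = config$batchSize)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- perm[starts[bi]:min(starts[bi] + config$batchSize - 1, nTr)]
      fg <- .lossAndGrads(
        params, modelConfig, graph, prep,
        trIdx$ci[rows], trIdx$ai[rows], yTr[rows],
        trIdx$degC[rows], trIdx$degA[rows], training = TRUE
      )
      losses[bi] <- fg$loss
      cl <- .clipGrads(fg$grads, config$clipNorm)
      stepT <- stepT + 1L
      upd <- .adamwStep(params, cl$grads, adamM, adamV, lr,
                        config$weightDecay, stepT)
      params <- upd$params
      adamM <- upd$m
      adamV <- upd$v
    }
    valP <- .predictIdx(params, modelConfig, graph, prep, vaIdx)
    valAuroc <- aurocScore(valP, split$val$label)
    logRows[[epoch]] <- data.frame(
      epoch = epoch, loss = mean(losses), valAuroc = valAuroc, lr = lr
    )
    if (valAuroc > best + 1e-8) {
      best <- valAuroc
      bestParams <- params
      bestEpoch <- epoch
      badEpochs <- 0L
      schedBad <- 0L
    } else {
      badEpochs <- badEpochs + 1L
      schedBad <- schedBad + 1L
      if (schedBad >= config$schedulerPatience) {
        lr <- lr * config$schedulerFactor
        schedBad <- 0L
      }
    }
    if (badEpochs >= config$earlyStopPatience) break
  }

  model <- methods::new("MsatModel",
    config = modelConfig, params = bestParams,
    meta = list(
      seed = config$seed, bestEpoch = bestEpoch, valAuroc = best,
      degStats = list(
        CMM = list(mu = degFeat$CMM$mu, sd = degFeat$CMM$sd),
        ADR = list(mu = degFeat$ADR$mu, sd = degFeat$ADR$sd)
      ),
      evidence = evidenceTable
    )
  )
  list(model = model, log = do.call(rbind, logRows[!vapply(logRows, is.null, logical(1))]))
}

#' Score CMM-ADR pairs with a trained model
#'
#' Deterministic evaluation-mode prediction: encodes the graph (dropout
#' off), applies the hub-calibrated scorer to each pair, and returns
#' probabilities in (0, 1). Degree features are standardized with the
#' statistics stored at training time.
#'
#' @param model a [MsatModel-class] from [trainFold()].
#' @param graph the fold's training graph (same as used in training).
#' @param pairs `data.frame` with columns `cmm_id`, `adr_id`.
#' @param evidenceTable evidence table; defaults to the one stored in the
#'   model.
#' @return `pairs` with an added `score` column.
#' @export
predictPairs <- function(model, graph, pairs, evidenceTable = NULL) {
  if (is.null(evidenceTable)) evidenceTable <- model@meta$evidence
  prep <- .prepareEncoderGraph(graph, evidenceTable)
  ds <- model@meta$degStats
  degFeat <- list(
    CMM = list(z = (log1p(.degreesOfType(graph, "CMM")) - ds$CMM$mu) / ds$CMM$sd),
    ADR = list(z = (log1p(.degreesOfType(graph, "ADR")) - ds$ADR$mu) / ds$ADR$sd)
  )
  idx <- .pairIndex(graph, pairs, degFeat)
  pairs$score <- .predictIdx(model@params, model@config, graph, prep, idx)
  pairs
}
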