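# End-to-end orchestration: cross-validated training/evaluation with
# leakage audits, imbalance stress evaluation, cold-start transfer, and
# ranked prediction with TCM annotation.

# Fit the evidence scaler on the fold's training edges and build scaled
# vectors for every edge remaining in the fold graph.
.foldEvidence <- function(foldGraph, trainPairs) {
  raw <- evidenceFeatureTable(foldGraph)
  key <- paste(raw$cmm_id, raw$adr_id, sep = "\r")
  trKey <- paste(trainPairs$cmm_id, trainPairs$adr_id, sep = "\r")
  trainRaw <- raw[key %in% trKey, , drop = FALSE]
  scaler <- fitEvidenceScaler(trainRaw)
  list(evidence = buildEvidenceVectors(foldGraph, scaler), scaler = scaler)
}

# Assemble one fold's labeled splits with cached type-constrained negatives.
.foldSplits <- function(plan, adrIds, negativeRatio) {
  posAll <- rbind(
    plan$train[, c("cmm_id", "adr_id")],
    plan$val[, c("cmm_id", "adr_id")],
    plan$test[, c("cmm_id", "adr_id")]
  )
  mk <- function(pos, offset) {
    neg <- sampleNegatives(pos,
      adrIds = adrIds, ratio = negativeRatio,
      seed = plan$seed + offset, positivesAll = posAll
    )
    rbind(
      pos[, c("cmm_id", "adr_id", "label")],
      neg[, c("cmm_id", "adr_id", "label")]
    )
  }
  list(
    train = mk(plan$train, 100L),
    val = mk(plan$val, 200L),
    test = mk(plan$test, 300L)
  )
}

#' Cross-validated training and evaluation
#'
#' Runs the full fold-wise protocol: stratified fold plans, bidirectional
#' removal of each fold's test positives from the graph (with a leakage
#' audit that aborts the run on failure), training-fold evidence scaling,
#' cached type-constrained negative sampling, model training with early
#' stopping on validation AUROC, and test-fold evaluation at a fixed
#' threshold of 0.5. Results are reported per fold and aggregated as
#' arithmetic mean and sample standard deviation.
#'
#' @param graph full [HeteroGraph-class] including all positive CMM-ADR
#'   edges.
#' @param positives positive association table (`cmm_id`, `adr_id`, plus
#'   attributes).
#' @param k number of folds.
#' @param modelConfig an [msatConfig()].
#' @param trainCfg an [trainConfig()]; fold `f` trains with seed
#'   `trainCfg$seed + f`.
#' @param negativeRatio negatives per positive in train/val/test.
#' @param seed seed for fold assignment and negative sampling.
#' @param threshold decision threshold for the threshold-dependent metrics.
#' @param keepModels keep the trained [MsatModel-class] per fold.
#' @return list with `folds` (per-fold metrics, logs, optionally models),
#'   `summary` (`data.frame` of mean and sd per metric) and `scores`
#'   (pooled out-of-fold score table).
#' @export
runCv <- function(graph, positives, k = 10L, modelConfig = msatConfig(),
                  trainCfg = trainConfig(), negativeRatio = 1L, seed = 42L,
                  threshold = 0.5, keepModels = FALSE) {
  plans <- makeFoldPlans(positives, k = k, seed = seed)
  adrIds <- nodeIds(graph, "ADR")
  folds <- vector("list", k)
  scoreTables <- vector("list", k)
  for (f in seq_len(k)) {
    plan <- plans[[f]]
    foldGraph <- removePairEdges(graph, data.frame(
      cmm_id = plan$test$cmm_id, adr_id = plan$test$adr_id
    ))
    auditLeakage(foldGraph, data.frame(
      cmm_id = plan$test$cmm_id, adr_id = plan$test$adr_id
    ))
    ev <- .foldEvidence(foldGraph, plan$train)
    splits <- .foldSplits(plan, adrIds, negativeRatio)
    foldTrainCfg <- trainCfg
    foldTrainCfg$seed <- trainCfg$seed + plan$foldId + 1L
    fit <- trainFold(foldGraph, ev$evidence,
                     splits[c("train", "val")], modelConfig, foldTrainCfg)
    scored <- predictPairs(fit$model, foldGraph, splits$test)
    m <- computeMetrics(scored$score, scored$label, threshold)
    scored$fold <- plan$foldId
    scoreTables[[f]] <- scored
    folds[[f]] <- list(
      foldId = plan$foldId, metrics = m, log = fit$log,
      model = if (keepModels) fit$model else NULL,
      plan = plan
    )
  }
  metricNames <- c("precision", "recall", "f1", "mcc", "auroc", "auprc")
  vals <- sapply(metricNames, function(nm) {
    vapply(folds, function(x) x$metrics[[nm]], numeric(1))
  })
  summary <- data.frame(
    metric = metricNames,
    mean = colMeans(vals),
    sd = apply(vals, 2, stats::sd),
    row.names = NULL
  )
  list(folds = folds, summary = summary, scores = do.call(rbind, scoreTables))
}

#' Imbalance stress evaluation of a trained fold model
#'
#' For each negative:positive ratio, builds a ratio-matched validation set
#' (fresh type-constrained negatives at that ratio), selects the
#' F1-maximizing threshold on it, and applies the threshold unchanged to
#' the nested ratio test set from [makeImbalanceTestsets()].
#'
#' @param model trained [MsatModel-class] for the fold.
#' @param graph the fold's training graph.
#' @param plan the fold plan.
#' @param adrIds full ADR vocabulary.
#' @param ratios negative:positive ratios.
#' @param seed integer seed.
#' @return named list per ratio: `threshold`, `metrics`, `testSet`.
#' @export
evaluateImbalance <- function(model, graph, plan, adrIds,
                              ratios = c(1L, 2L, 5L, 10L), seed = 42L) {
  posAll <- rbind(
    plan$train[, c("cmm_id", "adr_id")],
    plan$val[, c("cmm_id", "adr_id")],
    plan$test[, c("cmm_id", "adr_id")]
  )
  testSets <- makeImbalanceTestsets(plan, adrIds,
    ratios = ratios, seed = seed
  )
  out <- lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    valNeg <- sampleNegatives(plan$val,
      adrIds = adrIds, ratio = r,
      seed = seed + 7L * r, positivesAll = posAll
    )
    valSet <- rbind(
      plan$val[, c("cmm_id", "adr_id", "label")],
      valNeg[, c("cmm_id", "adr_id", "label")]
    )
    valScored <- predictPairs(model, graph, valSet)
    tau <- selectThreshold(valScored$score, valScored$label)
    teScored <- predictPairs(model, graph, testSets[[i]])
    list(
      threshold = tau,
      metrics = computeMetrics(teScored$score, teScored$label, tau),
      testSet = testSets[[i]]
    )
  })
  names(out) <- names(testSets)
  out
}

#' Cold-start source-transfer experiment
#'
#' Trains exclusively on FAERS-derived positives (split 90/10 into
#' train/validation) with the literature positives held out -- and removed
#' from the graph in both directions -- then evaluates on the literature
#' pairs against 1:1 sampled negatives. Reports the unseen-CMM fraction of
#' the test split.
#'
#' @inheritParams runCv
#' @return list with `metrics`, `unseenCmmFraction`, `model`, `log`.
#' @export
runColdStart <- function(graph, positives, modelConfig = msatConfig(),
                         trainCfg = trainConfig(), seed = 42L) {
  cs <- coldStartSplit(positives)
  foldGraph <- removePairEdges(graph, data.frame(
    cmm_id = cs$test$cmm_id, adr_id = cs$test$adr_id
  ))
  auditLeakage(foldGraph, data.frame(
    cmm_id = cs$test$cmm_id, adr_id = cs$test$adr_id
  ))
  set.seed(seed)
  nVal <- max(1L, round(0.1 * nrow(cs$train)))
  valRows <- sample.int(nrow(cs$train), nVal)
  trainPos <- cs$train[-valRows, , drop = FALSE]
  valPos <- cs$train[valRows, , drop = FALSE]
  posAll <- rbind(
    trainPos[, c("cmm_id", "adr_id")],
    valPos[, c("cmm_id", "adr_id")],
    cs$test[, c("cmm_id", "adr_id")]
  )
  adrIds <- nodeIds(graph, "ADR")
  mk <- function(pos, offset) {
    neg <- sampleNegatives(pos,
      adrIds = adrIds, ratio = 1L, seed = seed + offset,
      positivesAll = posAll
    )
    rbind(pos[, c("cmm_id", "adr_id", "label")],
          neg[, c("cmm_id", "adr_id", "label")])
  }
  ev <- .foldEvidence(foldGraph, trainPos)
  fit <- trainFold(foldGraph, ev$evidence,
                   list(train = mk(trainPos, 100L), val = mk(valPos, 200L)),
                   modelConfig, trainCfg)
  testSet <- mk(cs$test, 300L)
  scored <- predictPairs(fit$model, foldGraph, testSet)
  list(
    metrics = computeMetrics(scored$score, scored$label, 0.5),
    unseenCmmFraction = cs$unseenCmmFraction,
    model = fit$model, log = fit$log
  )
}

#' Rank candidate CMM-ADR predictions
#'
#' Scores candidate pairs absent from the labeled positives, returns them
#' in descending score order with ranks, and (optionally) annotates each
#' row with TCM functional systems. The default candidate universe is the
#' full CMM x ADR grid minus the known positives.
#'
#' @param model trained [MsatModel-class].
#' @param graph the training graph the model was fitted on.
#' @param knownPositives `data.frame` of labeled positive pairs.
#' @param candidates optional explicit candidate pair table; known
#'   positives are always excluded.
#' @param rules optional [TcmRuleSet-class] for annotation.
#' @param ptToSoc optional PT -> SOC table (required with `rules`).
#' @param cap optional maximum number of candidates scored (top by order of
#'   construction; a safeguard for very large grids).
#' @return ranked `data.frame` with `rank` and `score` columns.
#' @export
rankPredictions <- function(model, graph, knownPositives, candidates = NULL,
                            rules = NULL, ptToSoc = NULL, cap = NULL) {
  if (is.null(candidates)) {
    candidates <- expand.grid(
      cmm_id = nodeIds(graph, "CMM"), adr_id = nodeIds(graph, "ADR"),
      stringsAsFactors = FALSE
    )
  }
  key <- paste(candidates$cmm_id, candidates$adr_id, sep = "\r")
  posKey <- paste(knownPositives$cmm_id, knownPositives$adr_id, sep = "\r")
  candidates <- candidates[!(key %in% posKey), , drop = FALSE]
  if (!is.null(cap) && nrow(candidates) > cap) {
    candidates <- candidates[seq_len(cap), , drop = FALSE]
  }
  if (nrow(candidates) == 0) {
    candidates$score <- numeric(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  scored <- predictPairs(model, graph, candidates)
  scored <- scored[order(-scored$score), , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  if (!is.null(rules)) {
    .check(!is.null(ptToSoc), "ptToSoc table required for TCM annotation")
    scored <- mapPredictions(scored, rules, ptToSoc)
  }
  scored
}

#' Uniformly sample a rank stratum
#'
#' Draws `n` predictions uniformly at random (seeded) from the rows with
#' rank in `[from, to]`, for reliability assessment beyond the extreme top
#' of the ranking.
#'
#' @param ranked output of [rankPredictions()].
#' @param from,to inclusive rank bounds.
#' @param n sample size.
#' @param seed integer seed.
#' @return sampled rows, ordered by rank.
#' @export
sampleRankStratum <- function(ranked, from, to, n, seed = 42L) {
  pool <- ranked[ranked$rank >= from & ranked$rank <= to, , drop = FALSE]
  .check(nrow(pool) >= n, "stratum [%d, %d] has only %d rows", from, to, nrow(pool))
  set.seed(seed)
  out <- pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
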