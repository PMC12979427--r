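# Experimental machinery: stratified k-fold plans with leakage control,
# type-constrained negative sampling, threshold selection, classification
# metrics, imbalance stress sets, degree strata, cold-start splits and
# paired fold-wise tests.

#' Build stratified cross-validation fold plans
#'
#' Partitions the positive pairs into `k` folds of near-equal size
#' (differing by at most one). For each fold, the remaining development
#' positives are split 90/10 into train/validation with the fold's own
#' derived seed, yielding the overall ~81:9:10 train/validation/test split
#' at `k = 10`. Fully deterministic given `seed`.
#'
#' @param positives `data.frame` of positive pairs (columns `cmm_id`,
#'   `adr_id`, and optionally `provenance` etc., carried through).
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of fold plans; each plan is a list with `foldId` (0-based),
#'   `train`, `val`, `test` (label-1 pair tables) and `seed`.
#' @export
makeFoldPlans <- function(positives, k = 10L, seed = 42L) {
  n <- nrow(positives)
  .check(n >= k, "need at least k positives (%d < %d)", n, k)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  bounds <- c(0L, cumsum(sizes))
  lapply(seq_len(k), function(f) {
    testRows <- perm[(bounds[f] + 1):bounds[f + 1]]
    devRows <- setdiff(perm, testRows)
    foldSeed <- seed + f
    set.seed(foldSeed)
    nVal <- round(0.1 * length(devRows))
    valRows <- sample(devRows, nVal)
    trainRows <- setdiff(devRows, valRows)
    mk <- function(rows) {
      df <- positives[rows, , drop = FALSE]
      df$label <- 1L
      rownames(df) <- NULL
      df
    }
    list(
      foldId = f - 1L,
      train = mk(trainRows), val = mk(valRows), test = mk(testRows),
      seed = foldSeed
    )
  })
}

#' Type-constrained negative sampling
#'
#' For each positive pair `(h, a)`, fixes the CMM `h` and samples up to
#' `ratio` alternative ADRs uniformly from the admissible set: the full ADR
#' vocabulary minus the CMM's known positives (the fold's train/val/test
#' union) and minus any additional excluded pairs. Duplicates for the same
#' positive cannot occur (sampling without replacement); when a CMM's
#' admissible set is exhausted, fewer negatives are returned with a
#' warning. Deterministic given `seed`, so cached negative sets are
#' bit-identical across models.
#'
#' @param positives `data.frame` of the positives to pair negatives with
#'   (columns `cmm_id`, `adr_id`).
#' @param positivesAll `data.frame` of the full positive union used for
#'   collision filtering (defaults to `positives`).
#' @param adrIds character vector: the full ADR set.
#' @param ratio negatives per positive.
#' @param seed integer seed.
#' @param exclude optional `data.frame` of additional forbidden pairs
#'   (e.g. train/validation negatives when building test stress sets).
#' @return `data.frame` with columns `cmm_id`, `adr_id`, `label` (0) and
#'   `pos_row` (index of the anchoring positive; negatives are ordered by
#'   draw so that the first `r` per positive form the nested ratio-`r`
#'   subset).
#' @export
sampleNegatives <- function(positives, adrIds, ratio = 1L,
                            seed = 42L, positivesAll = positives,
                            exclude = NULL) {
  .check(length(adrIds) > 0, "adr set must be non-empty")
  set.seed(seed)
  posKey <- paste(positivesAll$cmm_id, positivesAll$adr_id, sep = "\r")
  exKey <- if (!is.null(exclude) && nrow(exclude)) {
    paste(exclude$cmm_id, exclude$adr_id, sep = "\r")
  } else {
    character(0)
  }
  forbidden <- c(posKey, exKey)
  out <- vector("list", nrow(positives))
  short <- 0L
  for (i in seq_len(nrow(positives))) {
    h <- as.character(positives$cmm_id[i])
    adm <- adrIds[!(paste(h, adrIds, sep = "\r") %in% forbidden)]
    nDraw <- min(ratio, length(adm))
    if (nDraw < ratio) short <- short + 1L
    if (nDraw == 0) next
    draw <- if (length(adm) == 1) adm else sample(adm, nDraw)
    out[[i]] <- data.frame(
      cmm_id = h, adr_id = draw, label = 0L, pos_row = i,
      stringsAsFactors = FALSE
    )
  }
  if (short > 0) {
    warning(sprintf(
      "admissible ADR set exhausted for %d positive(s); fewer negatives returned",
      short
    ), call. = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(
      cmm_id = character(0), adr_id = character(0),
      label = integer(0), pos_row = integer(0), stringsAsFactors = FALSE
    )
  }
  rownames(res) <- NULL
  res
}

#' Area under the ROC curve (rank statistic)
#'
#' Midrank-based AUROC, equal to the pairwise concordance probability with
#' half-credit for ties. `NA` when only one class is present.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\] or `NA`.
#' @export
aurocScore <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the sum over ranked positives of
#' precision at that rank times the recall increment. `NA` when only one
#' class is present.
#'
#' @inheritParams aurocScore
#' @return AUPRC in \[0, 1\] or `NA`.
#' @export
auprcScore <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(-scores)
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / n1
}

#' Threshold-dependent and threshold-free classification metrics
#'
#' Binarizes at `score >= threshold` and reports precision, recall, F1 and
#' the Matthews correlation coefficient together with rank-based AUROC and
#' average-precision AUPRC and the confusion counts. MCC is 0 when its
#' denominator vanishes; precision/recall are `NA` when undefined.
#'
#' @inheritParams aurocScore
#' @param threshold decision threshold (default 0.5, the main protocol).
#' @return list of class `msatMetrics`.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  .check(length(scores) == length(labels) && length(scores) >= 1,
         "scores and labels must be equal-length and non-empty")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  } else {
    0
  }
  out <- list(
    precision = precision, recall = recall, f1 = f1, mcc = mcc,
    auroc = aurocScore(scores, labels), auprc = auprcScore(scores, labels),
    tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold,
    n = length(scores)
  )
  class(out) <- "msatMetrics"
  out
}

#' @export
print.msatMetrics <- function(x, ...) {
  cat(sprintf(
    "metrics @ threshold %.4g: P=%.4f R=%.4f F1=%.4f MCC=%.4f AUROC=%.4f AUPRC=%.4f\n",
    x$threshold, x$precision, x$recall, x$f1, x$mcc, x$auroc, x$auprc
  ))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d (n=%d)\n", x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

#' Select the F1-maximizing decision threshold on validation data
#'
#' Evaluates F1 on the exhaustive grid of unique observed scores and
#' returns the maximizer; ties are broken toward the smaller threshold.
#' The threshold is chosen solely on validation data and applied unchanged
#' to the matched test set.
#'
#' @param valScores,valLabels validation scores and 0/1 labels (both
#'   classes required).
#' @return the selected threshold.
#' @export
selectThreshold <- function(valScores, valLabels) {
  .check(length(unique(valLabels)) == 2,
         "threshold selection requires both classes in validation")
  grid <- sort(unique(valScores))
  f1s <- vapply(grid, function(tau) {
    m <- computeMetrics(valScores, valLabels, tau)
    if (is.na(m$f1)) 0 else m$f1
  }, numeric(1))
  grid[which.max(f1s)] # which.max returns the first (smallest tau) maximizer
}

#' Degree-stratified CMM grouping
#'
#' Ranks CMMs by degree (descending, ties broken by node id for stability)
#' and partitions them 20/60/20 into Head (top `ceil(0.2 n)`), Tail
#' (bottom `ceil(0.2 n)`) and Medium (rest).
#'
#' @param cmmDegrees named numeric vector: CMM id -> degree.
#' @return `data.frame` with columns `cmm_id`, `degree`, `group`.
#' @export
degreeStrata <- function(cmmDegrees) {
  n <- length(cmmDegrees)
  .check(n >= 5, "degree stratification needs at least 5 CMMs")
  ord <- order(-cmmDegrees, names(cmmDegrees))
  nHead <- ceiling(0.2 * n)
  nTail <- ceiling(0.2 * n)
  group <- rep("Medium", n)
  group[seq_len(nHead)] <- "Head"
  group[(n - nTail + 1):n] <- "Tail"
  data.frame(
    cmm_id = names(cmmDegrees)[ord],
    degree = as.numeric(cmmDegrees[ord]),
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Imbalance stress test sets
#'
#' For each requested negative:positive ratio, keeps all of the fold's test
#' positives and pairs them with type-constrained negatives sampled from
#' unseen non-edges, avoiding the fold's full positive union and any pair
#' already used as a train/validation negative. Sets are nested
#' (ratio-1 set is a subset of the ratio-2 set, etc.) to reduce sampling
#' variance across ratios, and are generated once from a fixed seed.
#'
#' @param plan a fold plan from [makeFoldPlans()].
#' @param adrIds the full ADR vocabulary.
#' @param ratios integer vector of negative:positive ratios.
#' @param seed integer seed.
#' @param exclude optional `data.frame` of train/validation negative pairs
#'   to avoid.
#' @return named list (one element per ratio) of test `data.frame`s with
#'   columns `cmm_id`, `adr_id`, `label`.
#' @export
makeImbalanceTestsets <- function(plan, adrIds, ratios = c(1L, 2L, 5L, 10L),
                                  seed = 42L, exclude = NULL) {
  posAll <- rbind(
    plan$train[, c("cmm_id", "adr_id")],
    plan$val[, c("cmm_id", "adr_id")],
    plan$test[, c("cmm_id", "adr_id")]
  )
  maxRatio <- max(ratios)
  negs <- sampleNegatives(plan$test,
    adrIds = adrIds, ratio = maxRatio,
    seed = seed, positivesAll = posAll, exclude = exclude
  )
  # draw order within each positive defines the nested subsets
  drawIdx <- stats::ave(seq_len(nrow(negs)), negs$pos_row, FUN = seq_along)
  out <- lapply(ratios, function(r) {
    sub <- negs[drawIdx <= r, c("cmm_id", "adr_id", "label"), drop = FALSE]
    pos <- plan$test[, c("cmm_id", "adr_id")]
    pos$label <- 1L
    res <- rbind(pos, sub)
    rownames(res) <- NULL
    res
  })
  names(out) <- paste0("1:", ratios)
  out
}

#' Cold-start split across data sources
#'
#' Source-transfer protocol: trains on FAERS-derived statistical
#' associations only and holds out the expert-curated literature
#' associations as the test set, reporting the fraction of test CMMs that
#' never occur among the training positives (the unseen-CMM fraction).
#'
#' @param positives `data.frame` with columns `cmm_id`, `adr_id`,
#'   `provenance` (`"faers"` or `"literature"`).
#' @return list with `train`, `test` (pair tables with `label` = 1) and
#'   `unseenCmmFraction`.
#' @export
coldStartSplit <- function(positives) {
  tr <- positives[positives$provenance == "faers", , drop = FALSE]
  te <- positives[positives$provenance == "literature", , drop = FALSE]
  .check(nrow(tr) > 0, "cold-start split: no FAERS-derived positives")
  .check(nrow(te) > 0, "cold-start split: no literature positives")
  tr$label <- 1L
  te$label <- 1L
  unseen <- mean(!(unique(te$cmm_id) %in% tr$cmm_id))
  list(train = tr, test = te, unseenCmmFraction = unseen)
}

#' Paired fold-wise t test
#'
#' Two-sided paired t test on fold-wise metric values of two models
#' evaluated on identical splits. Zero variance of the differences is
#' flagged as degenerate rather than producing an undefined statistic.
#'
#' @param metricA,metricB numeric vectors of per-fold metric values (equal
#'   length >= 2).
#' @return list with `t`, `p`, `meanDiff` and `degenerate`.
#' @export
pairedFoldTest <- function(metricA, metricB) {
  .check(length(metricA) == length(metricB) && length(metricA) >= 2,
         "paired test needs equal-length vectors of at least 2 folds")
  d <- metricA - metricB
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, meanDiff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(metricA, metricB, paired = TRUE)
  list(
    t = unname(tt$statistic), p = tt$p.value,
    meanDiff = mean(d), degenerate = FALSE
  )
}

#' Persist fold plans as JSON
#'
#' @param plans list of fold plans from [makeFoldPlans()].
#' @param path output JSON path.
#' @export
saveFoldPlans <- function(plans, path) {
  jsonlite::write_json(plans, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
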