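# Evaluation protocols: fold arithmetic, negative sampling contracts,
# metric oracles, threshold selection, strata, stress sets, cold start,
# paired tests.

fakePositives <- function(n, nCmm = 12, nAdr = 20) {
  grid <- expand.grid(cmm_id = sprintf("h%02d", 1:nCmm),
                      adr_id = sprintf("a%02d", 1:nAdr),
                      stringsAsFactors = FALSE)
  set.seed(123)
  grid[sample(nrow(grid), n), ]
}

test_that("fold plans realize the 10-fold 81:9:10 split arithmetic", {
  pos <- fakePositives(100)
  plans <- makeFoldPlans(pos, k = 10, seed = 1)
  expect_length(plans, 10L)
  expect_true(all(vapply(plans, function(p) nrow(p$test), 0L) == 10L))
  expect_true(all(vapply(plans, function(p) nrow(p$val), 0L) == 9L))
  expect_true(all(vapply(plans, function(p) nrow(p$train), 0L) == 81L))
  # disjoint partition of positives across test folds
  allTest <- do.call(rbind, lapply(plans, `[[`, "test"))
  expect_equal(sort(paste(allTest$cmm_id, allTest$adr_id)),
               sort(paste(pos$cmm_id, pos$adr_id)))
  # within a fold, the three splits are disjoint
  for (p in plans[1:3]) {
    keys <- c(paste(p$train$cmm_id, p$train$adr_id),
              paste(p$val$cmm_id, p$val$adr_id),
              paste(p$test$cmm_id, p$test$adr_id))
    expect_equal(anyDuplicated(keys), 0L)
  }
  # determinism
  expect_identical(plans, makeFoldPlans(pos, k = 10, seed = 1))
  # remainder distribution for 101 positives
  plans101 <- makeFoldPlans(fakePositives(101, nCmm = 15), k = 10, seed = 2)
  sizes <- sort(vapply(plans101, function(p) nrow(p$test), 0L))
  expect_equal(sizes, c(rep(10L, 9), 11L))
  expect_error(makeFoldPlans(fakePositives(5), k = 10), "at least")
})

test_that("negative sampling is type-constrained, collision-free and seeded", {
  # single admissible candidate
  pos <- data.frame(cmm_id = "c1", adr_id = "a1")
  neg <- sampleNegatives(pos, adrIds = c("a1", "a2"), ratio = 1, seed = 3)
  expect_equal(neg$cmm_id, "c1")
  expect_equal(neg$adr_id, "a2")

  # exhaustion: a CMM positive with every ADR yields no negatives
  posAll <- data.frame(cmm_id = "c1", adr_id = c("a1", "a2"))
  expect_warning(
    negE <- sampleNegatives(posAll[1, ], adrIds = c("a1", "a2"), ratio = 1,
                            seed = 3, positivesAll = posAll),
    "exhausted"
  )
  expect_equal(nrow(negE), 0L)

  # ratio 10 with a wide ADR set: exactly 10 negatives per positive
  pos5 <- data.frame(cmm_id = "c1", adr_id = sprintf("a%03d", 1:5))
  neg10 <- sampleNegatives(pos5, adrIds = sprintf("a%03d", 1:100), ratio = 10,
                           seed = 4)
  expect_equal(nrow(neg10), 50L)
  expect_equal(as.integer(table(neg10$pos_row)), rep(10L, 5))
  # no duplicates for the same positive
  expect_equal(anyDuplicated(paste(neg10$pos_row, neg10$adr_id)), 0L)

  # exhaustive collision scan and seed reproducibility on a larger pool
  pos <- fakePositives(60)
  adrs <- sprintf("a%02d", 1:20)
  n1 <- sampleNegatives(pos, adrIds = adrs, ratio = 2, seed = 9)
  n2 <- sampleNegatives(pos, adrIds = adrs, ratio = 2, seed = 9)
  expect_identical(n1, n2)
  expect_false(any(paste(n1$cmm_id, n1$adr_id) %in%
                     paste(pos$cmm_id, pos$adr_id)))
  n3 <- sampleNegatives(pos, adrIds = adrs, ratio = 2, seed = 10)
  expect_false(identical(n1$adr_id, n3$adr_id))
})

test_that("computeMetrics matches the closed-form confusion arithmetic", {
  # perfect separation
  m <- computeMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)

  # formula oracle: tp=45 fp=5 tn=40 fn=10
  scores <- c(rep(0.9, 45), rep(0.9, 5), rep(0.1, 40), rep(0.1, 10))
  labels <- c(rep(1, 45), rep(0, 5), rep(0, 40), rep(1, 10))
  m2 <- computeMetrics(scores, labels, 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$tn, m2$fn), c(45, 5, 40, 10))
  expect_equal(m2$precision, 0.9)
  expect_equal(m2$recall, 9 / 11)
  expect_equal(m2$mcc, 1750 / sqrt(50 * 55 * 45 * 50))

  # balanced confusion gives MCC 0
  s3 <- c(0.9, 0.9, 0.1, 0.1)
  l3 <- c(1, 0, 1, 0)
  expect_equal(computeMetrics(s3, l3, 0.5)$mcc, 0)
  expect_error(computeMetrics(numeric(0), numeric(0)), "non-empty")
})

test_that("AUROC and AUPRC match brute-force oracles on random tables", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), 2) # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(aurocScore(scores, labels), bruteAuroc(scores, labels))
    # AUPRC oracle: direct precision-at-rank summation
    ord <- order(-scores)
    y <- labels[ord]
    ap <- sum((cumsum(y) / seq_along(y))[y == 1]) / sum(y)
    expect_equal(auprcScore(scores, labels), ap)
  }
})

test_that("threshold selection maximizes F1 on the exhaustive grid with the smaller-tau tie rule", {
  # worked tie case: F1 ties at tau = 0.3 and tau = 0.9
  scores <- c(0.9, 0.7, 0.5, 0.3)
  labels <- c(1, 0, 0, 1)
  grid <- sort(unique(scores))
  f1s <- vapply(grid, function(t) {
    m <- computeMetrics(scores, labels, t)
    m$f1
  }, numeric(1))
  expect_equal(max(f1s), 2 / 3)
  expect_equal(grid[f1s == max(f1s)], c(0.3, 0.9))
  expect_equal(selectThreshold(scores, labels), 0.3)

  # perfectly separated scores: the smallest grid value achieving F1 = 1
  s <- c(0.8, 0.7, 0.2, 0.1)
  l <- c(1, 1, 0, 0)
  expect_equal(selectThreshold(s, l), 0.7)

  # random instances agree with exhaustive-grid argmax
  set.seed(5)
  for (i in 1:4) {
    sc <- round(runif(50), 2)
    lb <- rbinom(50, 1, 0.5)
    if (length(unique(lb)) < 2) next
    g <- sort(unique(sc))
    f1g <- vapply(g, function(t) {
      x <- computeMetrics(sc, lb, t)$f1
      if (is.na(x)) 0 else x
    }, numeric(1))
    expect_equal(selectThreshold(sc, lb), g[which.max(f1g)])
  }
  expect_error(selectThreshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("degree strata partition 20/60/20 by rank with stable ties", {
  deg <- stats::setNames(1:10, sprintf("h%02d", 1:10))
  st <- degreeStrata(deg)
  expect_equal(st$cmm_id[st$group == "Head"], c("h10", "h09"))
  expect_equal(sort(st$cmm_id[st$group == "Tail"]), c("h01", "h02"))
  expect_equal(sum(st$group == "Medium"), 6L)

  # all-equal degrees: grouping is determined by the id tie-break
  eq <- stats::setNames(rep(3, 10), sprintf("h%02d", 1:10))
  stEq <- degreeStrata(eq)
  expect_equal(as.integer(table(stEq$group)[c("Head", "Medium", "Tail")]),
               c(2L, 6L, 2L))
  expect_equal(stEq$cmm_id[stEq$group == "Head"], c("h01", "h02"))

  # n = 5 gives ceil arithmetic 1/3/1
  st5 <- degreeStrata(stats::setNames(c(5, 4, 3, 2, 1), letters[1:5]))
  expect_equal(as.integer(table(st5$group)[c("Head", "Medium", "Tail")]),
               c(1L, 3L, 1L))
  expect_error(degreeStrata(stats::setNames(1:4, letters[1:4])), "at least 5")
})

test_that("imbalance test sets are nested, ratio-correct and deterministic", {
  pos <- fakePositives(60, nCmm = 10, nAdr = 40)
  plan <- makeFoldPlans(pos, k = 3, seed = 4)[[1]]
  adrs <- sprintf("a%02d", 1:40)
  sets <- makeImbalanceTestsets(plan, adrs, ratios = c(1, 2, 5, 10), seed = 6)
  nPos <- nrow(plan$test)
  for (r in c(1, 2, 5, 10)) {
    s <- sets[[paste0("1:", r)]]
    expect_equal(sum(s$label == 1), nPos)
    expect_lte(sum(s$label == 0), r * nPos)
    # negatives never collide with the fold's positive union
    posKey <- paste(pos$cmm_id, pos$adr_id)
    expect_false(any(paste(s$cmm_id, s$adr_id)[s$label == 0] %in% posKey))
  }
  key <- function(s) paste(s$cmm_id, s$adr_id)
  expect_true(all(key(sets[["1:1"]]) %in% key(sets[["1:2"]])))
  expect_true(all(key(sets[["1:2"]]) %in% key(sets[["1:5"]])))
  expect_true(all(key(sets[["1:5"]]) %in% key(sets[["1:10"]])))
  expect_identical(sets, makeImbalanceTestsets(plan, adrs,
                                               ratios = c(1, 2, 5, 10),
                                               seed = 6))
})

test_that("cold-start split separates sources and measures unseen CMMs", {
  # disjoint CMM supports: unseen fraction 1
  pos <- data.frame(
    cmm_id = c("h1", "h2", "h3", "h4"),
    adr_id = c("a1", "a2", "a3", "a4"),
    provenance = c("faers", "faers", "literature", "literature")
  )
  cs <- coldStartSplit(pos)
  expect_equal(cs$unseenCmmFraction, 1)
  expect_equal(nrow(cs$train), 2L)

  # fully overlapping supports: unseen fraction 0
  pos2 <- pos
  pos2$cmm_id <- c("h1", "h2", "h1", "h2")
  expect_equal(coldStartSplit(pos2)$unseenCmmFraction, 0)

  # mixed fixture equals brute-force set arithmetic
  set.seed(31)
  pos3 <- data.frame(
    cmm_id = sample(sprintf("h%d", 1:8), 40, TRUE),
    adr_id = sprintf("a%d", 1:40),
    provenance = sample(c("faers", "literature"), 40, TRUE)
  )
  cs3 <- coldStartSplit(pos3)
  teCmm <- unique(pos3$cmm_id[pos3$provenance == "literature"])
  trCmm <- unique(pos3$cmm_id[pos3$provenance == "faers"])
  expect_equal(cs3$unseenCmmFraction, mean(!(teCmm %in% trCmm)))
  expect_error(coldStartSplit(pos3[pos3$provenance == "faers", ]),
               "literature")
})

test_that("paired fold test matches the closed-form t statistic and flags degeneracy", {
  a <- c(0.9, 0.91, 0.92, 0.9, 0.93)
  expect_true(pairedFoldTest(a, a)$degenerate)

  # constant difference with tiny jitter: |t| large, p near 0
  set.seed(12)
  b <- a - 0.05 + rnorm(5, sd = 1e-4)
  res <- pairedFoldTest(a, b)
  expect_gt(abs(res$t), 100)
  expect_lt(res$p, 1e-6)
  # closed form: t = mean(d) / (sd(d) / sqrt(n))
  d <- a - b
  expect_equal(res$t, mean(d) / (stats::sd(d) / sqrt(5)))

  # symmetric differences: p well above any significance level
  set.seed(13)
  x <- runif(30)
  y <- x + sample(c(-1, 1), 30, TRUE) * 0.01
  expect_gt(pairedFoldTest(x, y)$p, 0.05)
})
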