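# Seeded generator of heterogeneous pharmacovigilance graphs with planted
# CMM-ADR associations. The label model mirrors the signals the encoder is
# built to exploit: association probability increases with mechanistic
# meta-path count and with the cosine similarity of the endpoint features,
# FAERS-like report counts are overdispersed and grow with meta-path
# support, and a configurable fraction of positives is literature-only.

#' Synthetic study configuration
#'
#' Defaults define a desk-scale study: 60 CMMs, 150 compounds, 300 targets
#' and 120 ADRs with mechanistic edge densities giving a few compounds per
#' CMM, a few targets per compound and sparse target-ADR links; a strongly
#' planted association signal (log-odds `b` per mechanistic meta-path and
#' `c` per unit feature cosine); negative-binomial report counts; and
#' clustered Gaussian node features shared across types so that feature
#' cosine is informative for true pairs.
#'
#' @param nCmm,nCompound,nTarget,nAdr node counts per type.
#' @param densities named list of Bernoulli edge densities for the
#'   mechanistic relations (`cmmCompound`, `compoundTarget`, `cmmTarget`,
#'   `targetTarget`, `targetAdr`).
#' @param positiveRate baseline association probability of a pair with no
#'   mechanistic meta-paths and orthogonal features (sets the label-model
#'   intercept `a = qlogis(positiveRate)`).
#' @param b log-odds increment per mechanistic meta-path.
#' @param c log-odds increment per unit feature cosine similarity.
#' @param reportDispersion negative-binomial size parameter of report
#'   counts (smaller = more overdispersed).
#' @param reportMeanBase mean report count of an unsupported positive;
#'   the mean scales with (1 + meta-path count).
#' @param literatureFraction probability that a positive is literature-only
#'   (count 0).
#' @param featureDim node feature width (shared across types so cosine is
#'   defined).
#' @param nLatentClusters number of latent feature clusters.
#' @param noiseSd per-dimension Gaussian noise around cluster centroids.
#' @param seed integer seed; fixes the full generated dataset.
#' @return list of class `msatSynthConfig`.
#' @export
synthConfig <- function(nCmm = 60L, nCompound = 150L, nTarget = 300L,
                        nAdr = 120L,
                        densities = list(
                          cmmCompound = 0.027, compoundTarget = 0.02,
                          cmmTarget = 0.005, targetTarget = 0.005,
                          targetAdr = 0.02
                        ),
                        positiveRate = 0.002, b = 1.5, c = 10,
                        reportDispersion = 1.5, reportMeanBase = 3,
                        literatureFraction = 0.05,
                        featureDim = 16L, nLatentClusters = 6L,
                        noiseSd = 0.15, seed = 42L) {
  .check(nCmm > 0 && nCompound > 0 && nTarget > 0 && nAdr > 0,
         "node counts must be positive")
  .check(all(unlist(densities) > 0 & unlist(densities) <= 1),
         "densities must lie in (0, 1]")
  .check(literatureFraction >= 0 && literatureFraction <= 1,
         "literatureFraction must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "msatSynthConfig"
  cfg
}

.bernoulliEdges <- function(n1, n2, p, symmetric = FALSE) {
  if (symmetric) {
    idx <- which(upper.tri(matrix(0, n1, n2)), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(src = seq_len(n1), dst = seq_len(n2)))
  }
  keep <- stats::runif(nrow(idx)) < p
  m <- idx[keep, , drop = FALSE]
  colnames(m) <- c("src", "dst")
  m
}

.clusterFeatures <- function(n, centroids, clusters, noiseSd) {
  centroids[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(centroids), sd = noiseSd), n)
}

#' Generate a synthetic heterogeneous study
#'
#' Samples mechanistic edges independently at the configured densities,
#' clustered node features, and planted CMM-ADR positives with
#' `P(positive) = plogis(a + b * metapath + c * cosine)`, where the
#' intercept `a` is calibrated so the mean linear predictor matches
#' `positiveRate`. FAERS-provenance positives receive negative-binomial
#' report counts with mean increasing in meta-path support;
#' literature-only positives receive count 0.
#'
#' @param config an [synthConfig()].
#' @return list with `graph` (a [HeteroGraph-class] including the CMM-ADR
#'   positive edges with `report_count`/`provenance` attributes), `pairs`
#'   (the positive association table), `truth` (all CMM x ADR pairs with
#'   meta-path count, cosine, true probability and label) and `config`.
#' @export
generateSyntheticData <- function(config) {
  .check(inherits(config, "msatSynthConfig"), "config must come from synthConfig()")
  set.seed(config$seed)
  ids <- list(
    CMM = sprintf("cmm%03d", seq_len(config$nCmm)),
    Compound = sprintf("cpd%03d", seq_len(config$nCompound)),
    Target = sprintf("tgt%03d", seq_len(config$nTarget)),
    ADR = sprintf("adr%03d", seq_len(config$nAdr))
  )
  d <- config$densities
  mech <- list(
    "CMM-Compound" = .bernoulliEdges(config$nCmm, config$nCompound, d$cmmCompound),
    "Compound-Target" = .bernoulliEdges(config$nCompound, config$nTarget, d$compoundTarget),
    "CMM-Target" = .bernoulliEdges(config$nCmm, config$nTarget, d$cmmTarget),
    "Target-Target" = .bernoulliEdges(config$nTarget, config$nTarget, d$targetTarget,
                                      symmetric = TRUE),
    "Target-ADR" = .bernoulliEdges(config$nTarget, config$nAdr, d$targetAdr)
  )
  edgeDfs <- lapply(names(mech), function(rel) {
    st <- .RELATIONS[[rel]]
    data.frame(
      src_id = ids[[st[1]]][mech[[rel]][, 1]],
      dst_id = ids[[st[2]]][mech[[rel]][, 2]],
      stringsAsFactors = FALSE
    )
  })
  names(edgeDfs) <- names(mech)

  # clustered features with centroids shared across types; orthonormal
  # centroids make cross-cluster cosine ~0 so that feature similarity is a
  # crisp planted signal
  K <- config$nLatentClusters
  .check(K <= config$featureDim,
         "nLatentClusters must not exceed featureDim (orthonormal centroids)")
  centroids <- t(qr.Q(qr(matrix(stats::rnorm(config$featureDim * K),
                                config$featureDim, K))))
  clusters <- lapply(ids, function(v) sample.int(K, length(v), replace = TRUE))
  features <- mapply(function(v, cl) {
    .clusterFeatures(length(v), centroids, cl, config$noiseSd)
  }, ids, clusters, SIMPLIFY = FALSE)

  # meta-path counts on the mechanistic skeleton
  skeleton <- heteroGraph(nodes = ids, edges = edgeDfs, features = features)
  mp <- metapathMatrix(skeleton)

  # feature cosine between every CMM and ADR
  fc <- features$CMM / sqrt(rowSums(features$CMM^2))
  fa <- features$ADR / sqrt(rowSums(features$ADR^2))
  cosMat <- fc %*% t(fa)

  a <- stats::qlogis(config$positiveRate)
  prob <- stats::plogis(a + config$b * mp + config$c * cosMat)
  label <- matrix(stats::rbinom(length(prob), 1, prob), nrow(prob))

  posIdx <- which(label == 1, arr.ind = TRUE)
  nPos <- nrow(posIdx)
  provenance <- ifelse(stats::runif(nPos) < config$literatureFraction,
                       "literature", "faers")
  mpPos <- mp[posIdx]
  counts <- integer(nPos)
  isFaers <- provenance == "faers"
  counts[isFaers] <- 1L + stats::rnbinom(
    sum(isFaers),
    size = config$reportDispersion,
    mu = config$reportMeanBase * (1 + mpPos[isFaers])
  )
  pairs <- data.frame(
    cmm_id = ids$CMM[posIdx[, 1]],
    adr_id = ids$ADR[posIdx[, 2]],
    report_count = counts,
    provenance = provenance,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$cmm_id, pairs$adr_id), , drop = FALSE]
  rownames(pairs) <- NULL

  edgeDfs[["CMM-ADR"]] <- data.frame(
    src_id = pairs$cmm_id, dst_id = pairs$adr_id,
    report_count = pairs$report_count, provenance = pairs$provenance,
    stringsAsFactors = FALSE
  )
  graph <- heteroGraph(nodes = ids, edges = edgeDfs, features = features)

  truth <- data.frame(
    cmm_id = rep(ids$CMM, times = config$nAdr),
    adr_id = rep(ids$ADR, each = config$nCmm),
    metapath = as.vector(mp),
    cosine = as.vector(cosMat),
    prob = as.vector(prob),
    label = as.vector(label),
    stringsAsFactors = FALSE
  )

  list(graph = graph, pairs = pairs, truth = truth, config = config)
}

#' Expand an association table into FAERS-like report records
#'
#' Inverse of the curation workflow for testing: each FAERS-provenance pair
#' becomes `report_count` report records with unique case ids. Optionally
#' injects superseded duplicate case versions (which
#' [dedupLatestVersion()] must remove) and contaminating records carrying a
#' blacklisted non-ADR term (which [filterNonAdr()] must remove), so that
#' curation of the generated records round-trips to the input pair table.
#'
#' @param pairTable association table (`cmm_id`, `adr_id` or `pt`,
#'   `report_count`, `provenance`).
#' @param versionDupFraction fraction of cases that additionally emit a
#'   stale lower-version record.
#' @param contamination number of blacklisted records to inject per 100
#'   true records (rate, may be 0).
#' @param blacklistPt the non-ADR term used for contamination.
#' @param meanDrugs mean excess co-reported drug count
#'   (`n_drugs_in_report` is 1 + Poisson(meanDrugs)).
#' @param seed integer seed.
#' @return `data.frame` of report records (`case_id`, `case_version`,
#'   `cmm_id`, `pt`, `n_drugs_in_report`).
#' @export
generateReportRecords <- function(pairTable, versionDupFraction = 0,
                                  contamination = 0,
                                  blacklistPt = "Product issues",
                                  meanDrugs = 0.8, seed = 42L) {
  set.seed(seed)
  pt <- if ("pt" %in% names(pairTable)) pairTable$pt else pairTable$adr_id
  faers <- pairTable$provenance == "faers" & pairTable$report_count > 0
  nRec <- sum(pairTable$report_count[faers])
  rows <- rep(which(faers), pairTable$report_count[faers])
  rec <- data.frame(
    case_id = sprintf("case%06d", seq_len(nRec)),
    case_version = rep(1L, nRec),
    cmm_id = pairTable$cmm_id[rows],
    pt = pt[rows],
    n_drugs_in_report = 1L + stats::rpois(nRec, meanDrugs),
    stringsAsFactors = FALSE
  )
  if (versionDupFraction > 0 && nRec > 0) {
    dup <- rec[stats::runif(nRec) < versionDupFraction, , drop = FALSE]
    if (nrow(dup) > 0) {
      # stale earlier versions of the same cases, pointing at a different
      # (superseded) reaction so that failing to deduplicate is detectable
      cur <- dup
      cur$case_version <- 2L
      rec$case_version[match(dup$case_id, rec$case_id)] <- 2L
      stale <- dup
      stale$case_version <- 1L
      stale$pt <- paste0(stale$pt, " (superseded)")
      rec <- rbind(rec, stale)
    }
  }
  nContam <- round(contamination / 100 * nRec)
  if (nContam > 0) {
    contam <- data.frame(
      case_id = sprintf("caseX%05d", seq_len(nContam)),
      case_version = 1L,
      cmm_id = sample(pairTable$cmm_id, nContam, replace = TRUE),
      pt = blacklistPt,
      n_drugs_in_report = 1L + stats::rpois(nContam, meanDrugs),
      stringsAsFactors = FALSE
    )
    rec <- rbind(rec, contam)
  }
  rownames(rec) <- NULL
  rec
}
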