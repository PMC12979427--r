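# Shared fixtures, built in code at test time.

# A small handcrafted graph: 2 CMMs, 2 compounds, 3 targets, 2 ADRs.
# cmm1 -> {cpd1, cpd2}; cpd1 -> {tgt1}; cpd2 -> {tgt2}; tgt1/tgt2 -> adr1;
# cmm1-adr1 and cmm2-adr2 are the label edges.
tinyGraph <- function(withFeatures = TRUE) {
  nodes <- list(
    CMM = c("cmm1", "cmm2"),
    Compound = c("cpd1", "cpd2"),
    Target = c("tgt1", "tgt2", "tgt3"),
    ADR = c("adr1", "adr2")
  )
  edges <- list(
    "CMM-Compound" = data.frame(src_id = c("cmm1", "cmm1"),
                                dst_id = c("cpd1", "cpd2")),
    "Compound-Target" = data.frame(src_id = c("cpd1", "cpd2"),
                                   dst_id = c("tgt1", "tgt2")),
    "Target-ADR" = data.frame(src_id = c("tgt1", "tgt2"),
                              dst_id = c("adr1", "adr1")),
    "CMM-ADR" = data.frame(
      src_id = c("cmm1", "cmm2"), dst_id = c("adr1", "adr2"),
      report_count = c(5L, 0L), provenance = c("faers", "literature")
    )
  )
  features <- NULL
  if (withFeatures) {
    set.seed(404)
    features <- lapply(nodes, function(ids) {
      matrix(rnorm(length(ids) * 4), length(ids), 4)
    })
  }
  heteroGraph(nodes = nodes, edges = edges,
              features = if (withFeatures) features else list())
}

# Small synthetic study used by the heavier modules.
smallSynth <- function(seed = 7, ...) {
  generateSyntheticData(synthConfig(
    nCmm = 20L, nCompound = 40L, nTarget = 60L, nAdr = 30L,
    densities = list(cmmCompound = 0.08, compoundTarget = 0.06,
                     cmmTarget = 0.01, targetTarget = 0.01, targetAdr = 0.06),
    featureDim = 8L, nLatentClusters = 4L, seed = seed, ...
  ))
}

# A tiny model/training configuration that runs in seconds.
tinyModelConfig <- function(...) {
  args <- utils::modifyList(
    list(heads = 2L, headDim = 4L, layers = 2L, dropout = 0,
         gateHidden = 8L, scorerHidden = 16L),
    list(...)
  )
  do.call(msatConfig, args)
}

tinyTrainConfig <- function(...) {
  args <- utils::modifyList(
    list(learningRate = 3e-3, batchSize = 256L, maxEpochs = 12L,
         earlyStopPatience = 8L, schedulerPatience = 4L, seed = 1L),
    list(...)
  )
  do.call(trainConfig, args)
}

# Layer parameters of the right shapes with every array set via `fill`.
toyLayerParams <- function(config, fill = function(dims) array(0, dims)) {
  p <- initMsatParams(config, stats::setNames(rep(2L, 4), msat:::.NODE_TYPES),
                      seed = 1L)
  p$layers[[1]]
}

# Evidence table covering the CMM-ADR edges of tinyGraph().
tinyEvidence <- function(graph = tinyGraph()) {
  buildEvidenceVectors(graph, fitEvidenceScaler(evidenceFeatureTable(graph)))
}

# Brute-force path enumeration oracle for metapath counts.
bruteMetapath <- function(graph, cmmId, adrId) {
  cc <- edgeTable(graph, "CMM-Compound")
  ct <- edgeTable(graph, "Compound-Target")
  ta <- edgeTable(graph, "Target-ADR")
  n <- 0L
  for (m in cc$dst_id[cc$src_id == cmmId]) {
    for (t in ct$dst_id[ct$src_id == m]) {
      if (any(ta$src_id == t & ta$dst_id == adrId)) n <- n + 1L
    }
  }
  n
}

# Brute-force pairwise concordance AUROC oracle.
bruteAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
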