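# Model configuration and parameter initialization for the multi-scale
# attention encoder and the hub-calibrated scorer.

#' Model configuration
#'
#' Hyperparameters of the encoder and scorer. Defaults follow the reference
#' configuration: 8 attention heads of per-head dimension 72 (hidden width
#' `heads * headDim = 576`), three attention layers, dropout 0.18 and a
#' six-dimensional edge-evidence vector. The hierarchical signal propagation
#' (HSP) block expands the hidden width by 2x then 3x before compressing
#' back (576 -> 1152 -> 1728 -> 576 at defaults).
#'
#' @param heads number of attention heads H.
#' @param headDim per-head embedding dimension d; the attention logits are
#'   scaled by `1/sqrt(headDim)`.
#' @param layers number of stacked attention layers L (>= 1).
#' @param dropout dropout rate in \[0, 1), applied to attention weights and
#'   the HSP output during training only.
#' @param evidenceDim length of the edge evidence vector (6).
#' @param gateHidden hidden width of the evidence-gate MLP branch.
#' @param scorerHidden hidden width of the degree-aware scorer MLP.
#' @param projBias logical; include bias in the type-specific input
#'   projections.
#' @return a list of class `msatConfig` with a derived `hidden = heads *
#'   headDim` element.
#' @export
msatConfig <- function(heads = 8L, headDim = 72L, layers = 3L, dropout = 0.18,
                       evidenceDim = 6L, gateHidden = 32L, scorerHidden = 256L,
                       projBias = TRUE) {
  .check(layers >= 1, "layers must be >= 1")
  .check(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  .check(heads >= 1 && headDim >= 1, "heads and headDim must be positive")
  cfg <- list(
    heads = as.integer(heads), headDim = as.integer(headDim),
    layers = as.integer(layers), dropout = dropout,
    evidenceDim = as.integer(evidenceDim),
    gateHidden = as.integer(gateHidden),
    scorerHidden = as.integer(scorerHidden),
    projBias = isTRUE(projBias),
    hidden = as.integer(heads) * as.integer(headDim)
  )
  class(cfg) <- "msatConfig"
  cfg
}

# Directed relation vocabulary: canonical relations plus materialized
# reverses. CMM-ADR edges (both directions) are biased by the evidence gate
# instead of the per-relation bias rows.
.directedRelationNames <- function() {
  c(names(.RELATIONS), paste0("rev:", names(.RELATIONS)))
}

#' Initialize model parameters
#'
#' Xavier-uniform initialization for all weight matrices, zeros for biases
#' and per-relation attention biases, gate scalar theta = 0 (gate = 0.5),
#' layer-norm gain 1 / shift 0, DistMult diagonal 1, fusion weights 1/3.
#' Parameters are fresh per layer (no weight tying) and fully determined by
#' `seed`.
#'
#' @param config an [msatConfig()].
#' @param featureDims named integer vector of input feature widths, one per
#'   node type (`CMM`, `Compound`, `Target`, `ADR`).
#' @param seed integer RNG seed.
#' @return nested parameter list with elements `proj`, `layers`, `scorer`.
#' @export
initMsatParams <- function(config, featureDims, seed = 42L) {
  .check(all(.NODE_TYPES %in% names(featureDims)),
         "featureDims must name all four node types")
  set.seed(seed)
  dh <- config$hidden
  H <- config$heads
  ev <- config$evidenceDim
  gh <- config$gateHidden

  proj <- lapply(.NODE_TYPES, function(ty) {
    list(
      W = .xavier(dh, featureDims[[ty]]),
      b = if (config$projBias) numeric(dh) else NULL
    )
  })
  names(proj) <- .NODE_TYPES

  nRel <- length(.directedRelationNames())
  layers <- lapply(seq_len(config$layers), function(l) {
    list(
      gate = list(
        theta = 0,
        Wg1 = .xavier(gh, ev), bg1 = numeric(gh),
        Wg2 = .xavier(H, gh), bg2 = numeric(H),
        Ws = .xavier(H, ev)
      ),
      relBias = matrix(0, nRel, H,
        dimnames = list(.directedRelationNames(), NULL)
      ),
      Wq = .xavier(dh, dh), Wk = .xavier(dh, dh), Wv = .xavier(dh, dh),
      W1 = .xavier(2L * dh, dh),
      W2 = .xavier(3L * dh, 2L * dh),
      W3 = .xavier(dh, 3L * dh),
      ln = list(gamma = rep(1, dh), beta = numeric(dh))
    )
  })

  scorer <- list(
    Wm1 = .xavier(config$scorerHidden, 2L * dh + 2L),
    bm1 = numeric(config$scorerHidden),
    wm2 = .xavier(1L, config$scorerHidden),
    bm2 = 0,
    WB = .xavier(dh, dh),
    r = rep(1, dh),
    w = c(1, 1, 1) / 3
  )

  list(proj = proj, layers = layers, scorer = scorer)
}

setMethod("show", "MsatModel", function(object) {
  cfg <- object@config
  cat("MsatModel\n")
  cat(sprintf(
    "  encoder: %d layer(s), %d head(s) x dim %d (hidden %d), dropout %.2f\n",
    cfg$layers, cfg$heads, cfg$headDim, cfg$hidden, cfg$dropout
  ))
  if (!is.null(object@meta$bestEpoch)) {
    cat(sprintf(
      "  best epoch %d, validation AUROC %.4f (seed %s)\n",
      object@meta$bestEpoch, object@meta$valAuroc,
      as.character(object@meta$seed)
    ))
  }
  invisible(NULL)
})

#' Persist / restore a trained model
#'
#' Writes the parameter arrays to an RDS-free plain representation: a JSON
#' config/meta sidecar plus a flat TSV of parameter values. Primarily a
#' checkpointing convenience for the command-line workflow.
#'
#' @param model a [MsatModel-class].
#' @param dir output directory.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- .flattenParams(model@params)
  jsonlite::write_json(
    list(
      config = unclass(model@config), meta = model@meta,
      shapes = lapply(flat, function(x) dim(x) %||% length(x))
    ),
    file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  vals <- unlist(lapply(flat, as.numeric), use.names = FALSE)
  utils::write.table(
    data.frame(value = vals), file.path(dir, "params.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  vals <- utils::read.delim(file.path(dir, "params.tsv"))$value
  cfg <- do.call(msatConfig, info$config[intersect(
    names(info$config), names(formals(msatConfig))
  )])
  featureDims <- stats::setNames(rep(1L, 4L), .NODE_TYPES) # placeholder shapes
  params <- initMsatParams(cfg, featureDims, seed = 0L)
  flat <- .flattenParams(params)
  # restore true shapes from the sidecar
  off <- 0L
  for (nm in names(info$shapes)) {
    sh <- unlist(info$shapes[[nm]])
    n <- prod(sh)
    x <- vals[(off + 1):(off + n)]
    off <- off + n
    flat[[nm]] <- if (length(sh) == 2) matrix(x, sh[1], sh[2]) else x
  }
  params <- .unflattenParams(flat, params)
  methods::new("MsatModel", config = cfg, params = params, meta = as.list(info$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a nested parameter tree into a named flat list (dotted paths;
# unnamed list elements, e.g. the per-layer blocks, use their index).
.elementName <- function(container, i) {
  nms <- names(container)
  if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
}

.flattenParams <- function(params, prefix = NULL) {
  out <- list()
  for (i in seq_along(params)) {
    x <- params[[i]]
    nm <- .elementName(params, i)
    path <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(x)) {
      out <- c(out, .flattenParams(x, path))
    } else if (!is.null(x)) {
      out[[path]] <- x
    }
  }
  out
}

.unflattenParams <- function(flat, skeleton, prefix = NULL) {
  for (i in seq_along(skeleton)) {
    nm <- .elementName(skeleton, i)
    path <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(skeleton[[i]])) {
      skeleton[[i]] <- .unflattenParams(flat, skeleton[[i]], path)
    } else if (!is.null(skeleton[[i]]) && !is.null(flat[[path]])) {
      skeleton[[i]] <- flat[[path]]
    }
  }
  skeleton
}
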