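# Hub-calibrated inference: weighted fusion of a degree-aware MLP score, a
# bilinear (asymmetric) score, and a DistMult (symmetric) score, mapped to a
# probability.

.asRowMatrix <- function(z) if (is.null(dim(z))) matrix(z, nrow = 1) else z

#' Degree-aware MLP score
#'
#' One-hidden-layer ReLU MLP over the concatenation
#' `[z_c || z_a || deg_c || deg_a]`. Degrees enter as standardized log1p
#' values computed from the fold's training graph, letting the scorer
#' calibrate hub-driven score inflation.
#'
#' @param zc,za embedding matrix/vector for the CMM and ADR side.
#' @param degC,degA standardized degree feature (scalar or vector).
#' @param scorerParams `params$scorer` from [initMsatParams()].
#' @return numeric score(s), one per pair.
#' @export
mlpScore <- function(zc, za, degC, degA, scorerParams) {
  zc <- .asRowMatrix(zc); za <- .asRowMatrix(za)
  .check(ncol(zc) == ncol(za), "embedding width mismatch")
  .check(ncol(scorerParams$Wm1) == 2 * ncol(zc) + 2,
         "scorer MLP expects width %d inputs, got %d",
         ncol(scorerParams$Wm1), 2 * ncol(zc) + 2)
  x <- cbind(zc, za, degC, degA)
  h <- .relu(sweep(x %*% t(scorerParams$Wm1), 2, scorerParams$bm1, "+"))
  drop(h %*% t(scorerParams$wm2) + scorerParams$bm2)
}

#' Bilinear (asymmetric) score
#'
#' `z_c^T W_B z_a`; a generic `W_B` makes the score directional, capturing
#' asymmetric CMM-to-ADR association patterns.
#'
#' @param zc,za embedding matrix/vector.
#' @param WB square bilinear matrix.
#' @return numeric score(s).
#' @export
bilinearScore <- function(zc, za, WB) {
  zc <- .asRowMatrix(zc); za <- .asRowMatrix(za)
  .check(ncol(zc) == nrow(WB) && ncol(za) == ncol(WB),
         "bilinear shape mismatch")
  drop(rowSums((zc %*% WB) * za))
}

#' DistMult (symmetric) score
#'
#' `sum_k z_c[k] r[k] z_a[k]`: the elementwise product contracted with a
#' learnable relation diagonal, invariant to swapping the two arguments.
#'
#' @param zc,za embedding matrix/vector.
#' @param r relation diagonal vector.
#' @return numeric score(s).
#' @export
distmultScore <- function(zc, za, r) {
  zc <- .asRowMatrix(zc); za <- .asRowMatrix(za)
  .check(ncol(zc) == length(r) && ncol(za) == length(r),
         "distmult shape mismatch")
  drop((zc * za) %*% r)
}

# Raw fused logit (pre-sigmoid), used by the training loss.
.hciLogit <- function(zc, za, degC, degA, sp) {
  sp$w[1] * mlpScore(zc, za, degC, degA, sp) +
    sp$w[2] * bilinearScore(zc, za, sp$WB) +
    sp$w[3] * distmultScore(zc, za, sp$r)
}

#' Hub-calibrated association probability
#'
#' Fuses the three scores with learnable weights,
#' `s = w1 * MLP + w2 * bilinear + w3 * DistMult`, and returns
#' `sigmoid(s)`, strictly inside (0, 1).
#'
#' @inheritParams mlpScore
#' @return probability (or vector of probabilities).
#' @export
hciScore <- function(zc, za, degC, degA, scorerParams) {
  .sigmoid(.hciLogit(zc, za, degC, degA, scorerParams))
}
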