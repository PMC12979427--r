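# Internal helpers shared across modules.

.NODE_TYPES <- c("CMM", "Compound", "Target", "ADR")

# Canonical relation schema: relation name -> c(source type, destination type).
.RELATIONS <- list(
  "CMM-Compound"    = c("CMM", "Compound"),
  "Compound-Target" = c("Compound", "Target"),
  "CMM-Target"      = c("CMM", "Target"),
  "Target-Target"   = c("Target", "Target"),
  "Target-ADR"      = c("Target", "ADR"),
  "CMM-ADR"         = c("CMM", "ADR")
)

.sigmoid <- function(x) 1 / (1 + exp(-x))

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @noRd
.emptyEdgeMatrix <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("src", "dst")))
}

# Xavier/Glorot uniform initialization for a (nrow x ncol) weight matrix.
.xavier <- function(nrow, ncol) {
  a <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -a, a), nrow = nrow, ncol = ncol)
}

# Recursive elementwise walk over two parameter trees with identical shape.
.mapParams <- function(f, a, b = NULL) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- .mapParams(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    out
  } else {
    if (is.null(b)) f(a) else f(a, b)
  }
}

# Sum of f(leaf) over a parameter tree.
.sumParams <- function(f, a) {
  if (is.null(a)) return(0)
  if (is.list(a)) sum(vapply(a, function(x) .sumParams(f, x), numeric(1)))
  else f(a)
}

.zerosLike <- function(a) .mapParams(function(x) x * 0, a)

#' Stop unless a condition holds
#' @noRd
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
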