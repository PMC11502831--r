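#' @keywords internal
"_PACKAGE"

## Half-vectorization helpers. vech order is column-major over the lower
## triangle including the diagonal: (1,1),(2,1),...,(p,1),(2,2),...

#' Half-vectorize a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) of a symmetric matrix
#' in column-major order.
#'
#' @param M symmetric numeric matrix.
#' @return numeric vector of length `p(p+1)/2`.
#' @export
vech <- function(M) M[lower.tri(M, diag = TRUE)]

#' Index map for vech order
#'
#' @param p matrix dimension.
#' @return two-column integer matrix; row `m` holds the (row, col) position
#'   of the `m`-th vech element.
#' @export
vech_index <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

#' Rebuild a symmetric matrix from its half-vectorization
#'
#' @param v vech vector.
#' @param p matrix dimension.
#' @return p x p symmetric matrix.
#' @export
unvech <- function(v, p) {
  stopifnot(length(v) == p * (p + 1) / 2)
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

## Eigen pseudoinverse with a relative tolerance; V from a block jackknife
## can be numerically singular (and is exactly singular in the directions of
## the unit diagonal of a standardized structure).
pseudoinverse <- function(V, tol = 1e-10) {
  e <- eigen(V, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(V), ncol(V)))
  U <- e$vectors[, keep, drop = FALSE]
  U %*% (t(U) / e$values[keep])
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
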