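## Exploratory factor analysis of a (smoothed) genetic correlation matrix:
## maximum-likelihood extraction with oblique promax rotation, used to
## propose the loading pattern that the confirmatory stage re-estimates on
## the other chromosome parity.

#' Exploratory factor analysis of a genetic correlation matrix
#'
#' Maximum-likelihood factor extraction followed by oblique promax (power
#' 4) rotation. Before rotation the unrotated loadings are passed through
#' a fixed small Givens pre-rotation so that exactly symmetric inputs do
#' not sit on a varimax saddle point; the pre-rotation is absorbed into
#' the reported rotation and changes nothing for generic inputs. Each
#' factor's sign is fixed so that its loading sum is positive. A solution
#' whose uniquenesses hit the estimator's lower bound (a Heywood case) is
#' flagged `converged = FALSE`.
#'
#' @param S_std standardized (correlation-metric) genetic covariance: a
#'   `covstruct` or a plain correlation matrix, smoothed to PSD.
#' @param n_factors number of factors to extract; must be < number of
#'   traits.
#' @return object of class `efa_result`: list with `n_factors`, `loadings`
#'   (p x k), `factor_correlations` (k x k), `eigenvalues` (of the input
#'   matrix), `uniquenesses`, `converged`, `diagnostic`.
#' @export
run_efa <- function(S_std, n_factors) {
  R <- if (inherits(S_std, "covstruct")) S_std$S else S_std
  p <- nrow(R)
  if (is.null(rownames(R))) dimnames(R) <- list(paste0("V", seq_len(p)),
                                                paste0("V", seq_len(p)))
  if (n_factors < 1 || n_factors >= p)
    stop("n_factors must be between 1 and p - 1 (p = ", p, ")")
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values

  fa <- tryCatch(
    stats::factanal(covmat = R, factors = n_factors, rotation = "none",
                    nstart = 3),
    error = function(e) e)
  if (inherits(fa, "error")) {
    return(structure(list(n_factors = n_factors, loadings = NULL,
                          factor_correlations = NULL,
                          eigenvalues = eigenvalues, uniquenesses = NULL,
                          converged = FALSE,
                          diagnostic = conditionMessage(fa)),
                     class = "efa_result"))
  }
  L <- stats::loadings(fa)
  class(L) <- NULL

  if (n_factors == 1) {
    Lr <- L
    Phi <- matrix(1, 1, 1)
  } else {
    ## fixed Givens pre-rotation between consecutive factor pairs breaks
    ## exact reflection symmetry (theta = 0.3 rad; deterministic)
    R0 <- diag(n_factors)
    for (f in seq_len(n_factors - 1)) {
      G <- diag(n_factors)
      G[f, f] <- cos(0.3); G[f + 1, f + 1] <- cos(0.3)
      G[f, f + 1] <- -sin(0.3); G[f + 1, f] <- sin(0.3)
      R0 <- R0 %*% G
    }
    pm <- stats::promax(structure(L %*% R0, class = "loadings"), m = 4)
    Lr <- unclass(pm$loadings)
    U <- R0 %*% pm$rotmat
    Phi <- solve(crossprod(U))
    Phi <- stats::cov2cor((Phi + t(Phi)) / 2)
  }

  ## sign convention: per-factor loading sum positive
  flip <- colSums(Lr) < 0
  Lr[, flip] <- -Lr[, flip]
  Phi[flip, ] <- -Phi[flip, ]
  Phi[, flip] <- -Phi[, flip]
  diag(Phi) <- 1

  dimnames(Lr) <- list(rownames(R), paste0("F", seq_len(n_factors)))
  dimnames(Phi) <- list(colnames(Lr), colnames(Lr))
  heywood <- any(fa$uniquenesses <= 0.005 + 1e-8)
  structure(list(n_factors = n_factors, loadings = Lr,
                 factor_correlations = Phi, eigenvalues = eigenvalues,
                 uniquenesses = fa$uniquenesses,
                 converged = !heywood,
                 diagnostic = if (heywood)
                   "Heywood case: uniqueness at lower bound" else NULL),
            class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("<efa_result> %d factor(s), converged = %s\n",
              x$n_factors, x$converged))
  if (!is.null(x$loadings)) print(round(x$loadings, 3))
  invisible(x)
}
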