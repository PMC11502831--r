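## The genetic covariance structure: a k x k genetic covariance matrix S,
## the q x q sampling covariance V of vech(S) (q = k(k+1)/2, column-major
## lower triangle), and the k x k LDSC intercept matrix (diagonal:
## univariate intercepts; off-diagonal: sample-overlap intercepts).

new_covstruct <- function(traits, S, V, intercepts, n_blocks,
                          standardized = FALSE, M = NA_real_) {
  k <- length(traits)
  dimnames(S) <- list(traits, traits)
  dimnames(intercepts) <- list(traits, traits)
  structure(list(traits = traits, S = S, V = V, intercepts = intercepts,
                 n_blocks = n_blocks, standardized = standardized, M = M),
            class = "covstruct")
}

#' @export
print.covstruct <- function(x, ...) {
  cat(sprintf("<covstruct> %d traits, %s metric, V from %d jackknife blocks\n",
              length(x$traits),
              if (x$standardized) "correlation" else "covariance",
              x$n_blocks))
  print(round(x$S, 3))
  invisible(x)
}

#' Joint genetic covariance structure by LD score regression
#'
#' Runs univariate LDSC on every trait and cross-trait LDSC on every pair,
#' assembling the genetic covariance matrix S, the intercept matrix, and
#' the full sampling covariance V of vech(S) by a joint delete-one-block
#' jackknife: leave-one-block-out slopes are computed for every element of
#' vech(S) over the same contiguous SNP blocks, so V captures sampling
#' covariance across elements.
#'
#' @param tables list of `sumstats` data.frames (named, or trait names are
#'   taken from their `trait_name` attributes), munged to a common
#'   reference.
#' @param ld an `ldscores` data.frame.
#' @param n_blocks number of jackknife blocks (default 200; at least 20).
#' @return a `covstruct` object.
#' @export
build_covariance_structure <- function(tables, ld, n_blocks = 200) {
  if (n_blocks < 20) stop("n_blocks must be at least 20")
  k <- length(tables)
  traits <- names(tables) %||%
    vapply(tables, function(t) attr(t, "trait_name"), character(1))
  if (is.null(names(tables))) names(tables) <- traits

  common <- Reduce(intersect, lapply(tables, function(t) t$snp))
  common <- intersect(common, ld$snp)
  if (length(common) < 200)
    stop("fewer than 200 SNPs shared across all traits and the LD scores")
  ord <- match(common, ld$snp)
  common <- common[order(ld$chr[ord], ld$bp[ord])]
  l2 <- pmax(ld$l2[match(common, ld$snp)], 1)
  M <- attr(ld, "M")
  nsnp <- length(common)
  blocks <- jackknife_blocks(nsnp, n_blocks)

  Z <- vapply(tables, function(t) t$z[match(common, t$snp)], numeric(nsnp))
  N <- vapply(tables, function(t) t$n[match(common, t$snp)], numeric(nsnp))
  if (any(!is.finite(Z))) stop("non-finite Z among the harmonized tables")

  ## univariate pass: final weights d_t and leave-one-out slopes
  uni <- vector("list", k)
  for (t in seq_len(k))
    uni[[t]] <- ldsc_irls(pmin(Z[, t]^2, CHI2_WINSOR), N[, t] * l2 / M, l2,
                          blocks = blocks)

  q <- k * (k + 1) / 2
  idx <- vech_index(k)
  loo <- matrix(NA_real_, n_blocks, q)
  S <- matrix(NA_real_, k, k)
  intercepts <- matrix(NA_real_, k, k)
  for (m in seq_len(q)) {
    i <- idx[m, 1]; j <- idx[m, 2]
    if (i == j) {
      fit <- uni[[i]]$fit
      S[i, i] <- unname(fit$coef["slope"])
      intercepts[i, i] <- unname(fit$coef["intercept"])
      loo[, m] <- fit$loo[, "slope"]
    } else {
      y <- pmin(pmax(Z[, i] * Z[, j], -CHI2_WINSOR), CHI2_WINSOR)
      x <- sqrt(N[, i] * N[, j]) * l2 / M
      w <- 1 / (l2 * uni[[i]]$d * uni[[j]]$d)
      fit <- wreg_jackknife(y, x, w, blocks)
      S[i, j] <- S[j, i] <- unname(fit$coef["slope"])
      intercepts[i, j] <- intercepts[j, i] <- unname(fit$coef["intercept"])
      loo[, m] <- fit$loo[, "slope"]
    }
  }
  ctr <- sweep(loo, 2, colMeans(loo))
  V <- (n_blocks - 1) / n_blocks * crossprod(ctr)
  new_covstruct(traits, S, V, intercepts, n_blocks, standardized = FALSE,
                M = M)
}

#' Standardize a genetic covariance structure to the correlation metric
#'
#' Rescales S to the genetic correlation matrix (unit diagonal) and
#' transforms V by the delta method for the rescaling map
#' `r_tu = s_tu / sqrt(s_tt s_uu)`. Idempotent: the sampling variance of
#' the (now exactly unit) diagonal becomes zero, and a second application
#' changes nothing.
#'
#' @param gs a `covstruct`.
#' @return standardized `covstruct`.
#' @export
standardize_structure <- function(gs) {
  if (isTRUE(gs$standardized)) return(gs)
  d <- diag(gs$S)
  if (any(d <= 0))
    stop("non-positive genetic variance for trait(s): ",
         paste(gs$traits[d <= 0], collapse = ", "))
  k <- length(gs$traits)
  q <- k * (k + 1) / 2
  idx <- vech_index(k)
  pos <- matrix(0L, k, k)
  pos[cbind(idx[, 1], idx[, 2])] <- seq_len(q)
  pos[cbind(idx[, 2], idx[, 1])] <- seq_len(q)

  R <- stats::cov2cor(gs$S)
  J <- matrix(0, q, q)
  for (m in seq_len(q)) {
    i <- idx[m, 1]; j <- idx[m, 2]
    if (i == j) next  # r_tt = 1 identically; zero row
    J[m, m] <- 1 / sqrt(d[i] * d[j])
    J[m, pos[i, i]] <- -R[i, j] / (2 * d[i])
    J[m, pos[j, j]] <- -R[i, j] / (2 * d[j])
  }
  V <- J %*% gs$V %*% t(J)
  new_covstruct(gs$traits, R, V, gs$intercepts, gs$n_blocks,
                standardized = TRUE, M = gs$M)
}

#' Smooth a symmetric matrix to positive semi-definiteness
#'
#' Clips eigenvalues below `eps` to `eps`, reconstitutes the matrix, and
#' re-normalizes it to unit diagonal. Returns the input unchanged when it
#' is already PSD. The maximum absolute element change is attached as
#' attribute `max_change`.
#'
#' @param S_std symmetric matrix (a correlation matrix in normal use).
#' @param eps eigenvalue floor (default 1e-6).
#' @return PSD matrix with attribute `max_change`.
#' @export
smooth_to_psd <- function(S_std, eps = 1e-6) {
  stopifnot(isSymmetric(unname(S_std), tol = 1e-8))
  e <- eigen(S_std, symmetric = TRUE)
  if (min(e$values) >= eps) {
    attr(S_std, "max_change") <- 0
    return(S_std)
  }
  vals <- pmax(e$values, eps)
  M <- e$vectors %*% (vals * t(e$vectors))
  M <- stats::cov2cor(M)
  dimnames(M) <- dimnames(S_std)
  attr(M, "max_change") <- max(abs(M - S_std))
  M
}

#' Smooth the S matrix of a covariance structure to PSD
#'
#' Convenience wrapper applying [smooth_to_psd()] to `gs$S` in place.
#'
#' @param gs a `covstruct`.
#' @param eps eigenvalue floor.
#' @return the `covstruct` with a PSD S.
#' @export
smooth_structure <- function(gs, eps = 1e-6) {
  S <- smooth_to_psd(gs$S, eps = eps)
  gs$S[, ] <- S
  attr(gs$S, "max_change") <- NULL
  gs$smoothing_max_change <- attr(S, "max_change")
  gs
}

## restrict a covstruct to a subset of traits, carving the matching rows
## and columns out of S, V and the intercepts
subset_covstruct <- function(gs, traits) {
  sel <- match(traits, gs$traits)
  if (any(is.na(sel)))
    stop("traits not in structure: ",
         paste(traits[is.na(sel)], collapse = ", "))
  k <- length(gs$traits)
  idx <- vech_index(k)
  pos_old <- matrix(0L, k, k)
  pos_old[cbind(idx[, 1], idx[, 2])] <- seq_len(nrow(idx))
  pos_old[cbind(idx[, 2], idx[, 1])] <- seq_len(nrow(idx))
  idx2 <- vech_index(length(sel))
  keep_el <- pos_old[cbind(sel[idx2[, 1]], sel[idx2[, 2]])]
  new_covstruct(traits,
                gs$S[sel, sel, drop = FALSE],
                gs$V[keep_el, keep_el, drop = FALSE],
                gs$intercepts[sel, sel, drop = FALSE],
                gs$n_blocks, standardized = gs$standardized, M = gs$M)
}
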