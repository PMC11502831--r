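## LD score regression: univariate and cross-trait fits, block-jackknife
## standard errors, and assembly of the joint (S, V) genetic covariance
## structure.
##
## Model: E[chi2_j]    = intercept + (N_j h2 / M) l_j             (univariate)
##        E[Z1_j Z2_j] = cross_intercept + (sqrt(N1_j N2_j) gcov / M) l_j
## fitted by iteratively reweighted least squares with heteroskedasticity
## weights 1 / [l_j d_j^2] where d_j = intercept + N_j h2 l_j / M is the
## fitted per-SNP conditional scale (cross-trait: 1 / [l_j d1_j d2_j]).

CHI2_WINSOR <- 80

## contiguous equal-count block assignment over n SNPs (sorted chrom/pos)
jackknife_blocks <- function(n, n_blocks) {
  if (n_blocks < 2) stop("need at least 2 jackknife blocks")
  as.integer(ceiling(seq_len(n) / (n / n_blocks)))
}

## weighted simple regression y ~ 1 + x with delete-one-block coefficients.
## Returns full-fit (intercept, slope) and an n_blocks x 2 matrix of
## leave-one-block-out coefficients, from per-block partial sums.
wreg_jackknife <- function(y, x, w, blocks) {
  parts <- cbind(w = w, wx = w * x, wxx = w * x^2, wy = w * y, wxy = w * x * y)
  bs <- rowsum(parts, blocks)
  tot <- colSums(bs)
  coef_from <- function(s) {
    det <- s["w"] * s["wxx"] - s["wx"]^2
    c(intercept = unname((s["wxx"] * s["wy"] - s["wx"] * s["wxy"]) / det),
      slope = unname((s["w"] * s["wxy"] - s["wx"] * s["wy"]) / det))
  }
  full <- coef_from(tot)
  loo <- t(apply(bs, 1, function(b) coef_from(tot - b)))
  colnames(loo) <- c("intercept", "slope")
  list(coef = full, loo = loo)
}

jackknife_se <- function(loo_col) {
  nb <- length(loo_col)
  sqrt((nb - 1) / nb * sum((loo_col - mean(loo_col))^2))
}

## merge a sumstats table with LD scores on snp id; preserves sort order
merge_ld <- function(table, ld) {
  m <- match(table$snp, ld$snp)
  keep <- !is.na(m)
  list(tab = as.data.frame(table)[keep, , drop = FALSE],
       l2 = pmax(ld$l2[m[keep]], 1))
}

## 3 reweighting iterations for one response vector given per-trait
## predictor pieces; returns final fit, weights and the d vectors
ldsc_irls <- function(chi2, x, l2, n_iter = 3, blocks) {
  h2 <- 0; int <- 1
  for (i in seq_len(n_iter)) {
    d <- pmax(int + h2 * x, 0.05)
    w <- 1 / (l2 * d^2)
    cf <- wreg_jackknife(chi2, x, w, blocks)$coef
    int <- cf["intercept"]; h2 <- cf["slope"]
  }
  d <- pmax(int + h2 * x, 0.05)
  w <- 1 / (l2 * d^2)
  fit <- wreg_jackknife(chi2, x, w, blocks)
  list(fit = fit, w = w, d = d)
}

#' Univariate LD score regression
#'
#' Estimates SNP heritability and the confounding intercept by regressing
#' association chi-square statistics on LD scores, with block-jackknife
#' standard errors. chi-square values above 80 are winsorized before the
#' regression; the intercept is estimated freely; the slope is
#' unconstrained, so `h2` may be negative for null traits.
#'
#' @param table a `sumstats` data.frame.
#' @param ld an `ldscores` data.frame (see [read_ldscores()]).
#' @param n_blocks number of contiguous jackknife blocks (default 200).
#' @return an object of class `ldsc_fit`: list with `h2`, `intercept`,
#'   `se_h2`, `se_intercept`, `n_snps_used`, `mean_chi2`, and the
#'   leave-one-block-out coefficients in `loo`.
#' @export
univariate_ldsc <- function(table, ld, n_blocks = 200) {
  mg <- merge_ld(table, ld)
  tab <- mg$tab
  chi2 <- tab$z^2
  ok <- is.finite(chi2)
  if (any(!ok)) {
    warning(sum(!ok), " non-finite chi-square values dropped")
    tab <- tab[ok, , drop = FALSE]; mg$l2 <- mg$l2[ok]; chi2 <- chi2[ok]
  }
  if (nrow(tab) < 200) stop("too few SNPs shared with the LD-score table (",
                            nrow(tab), " < 200)")
  chi2 <- pmin(chi2, CHI2_WINSOR)
  M <- attr(ld, "M")
  x <- tab$n * mg$l2 / M
  blocks <- jackknife_blocks(nrow(tab), n_blocks)
  res <- ldsc_irls(chi2, x, mg$l2, blocks = blocks)
  structure(list(h2 = unname(res$fit$coef["slope"]),
                 intercept = unname(res$fit$coef["intercept"]),
                 se_h2 = jackknife_se(res$fit$loo[, "slope"]),
                 se_intercept = jackknife_se(res$fit$loo[, "intercept"]),
                 n_snps_used = nrow(tab), mean_chi2 = mean(chi2),
                 loo = res$fit$loo, d = res$d),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit> h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d SNPs\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept, x$n_snps_used))
  invisible(x)
}

## shared-SNP alignment of two (already munged) tables; alleles must agree
harmonize_pair <- function(t1, t2) {
  common <- intersect(t1$snp, t2$snp)
  a <- as.data.frame(t1)[match(common, t1$snp), , drop = FALSE]
  b <- as.data.frame(t2)[match(common, t2$snp), , drop = FALSE]
  same <- a$a1 == b$a1 & a$a2 == b$a2
  swap <- a$a1 == b$a2 & a$a2 == b$a1
  b$z[swap] <- -b$z[swap]
  b$beta[swap] <- -b$beta[swap]
  keep <- same | swap
  list(t1 = a[keep, , drop = FALSE], t2 = b[keep, , drop = FALSE])
}

#' Cross-trait LD score regression
#'
#' Estimates the genetic covariance between two traits by regressing
#' per-SNP Z-score products on LD scores; the intercept absorbs sample
#' overlap. The genetic correlation is `gcov / sqrt(h2_1 h2_2)` using
#' univariate fits on the shared SNP set, clamped to `[-1, 1]` (with
#' `rg_clamped` flag), and reported as `NA` when either heritability
#' estimate is non-positive.
#'
#' @param t1,t2 `sumstats` data.frames, munged to a common reference.
#' @param ld an `ldscores` data.frame.
#' @param n_blocks number of jackknife blocks.
#' @return object of class `crosstrait_fit`: list with `gcov`, `rg`,
#'   `cross_intercept`, `se_gcov`, `se_rg`, `p_rg`, `rg_clamped`, and the
#'   per-trait univariate fits.
#' @export
bivariate_ldsc <- function(t1, t2, ld, n_blocks = 200) {
  hp <- harmonize_pair(t1, t2)
  a <- hp$t1; b <- hp$t2
  mg <- merge_ld(new_sumstats(a), ld)
  a <- a[match(mg$tab$snp, a$snp), ]; b <- b[match(mg$tab$snp, b$snp), ]
  l2 <- mg$l2
  if (nrow(a) < 200) stop("too few shared SNPs after harmonization (",
                          nrow(a), " < 200)")
  M <- attr(ld, "M")
  blocks <- jackknife_blocks(nrow(a), n_blocks)

  u1 <- ldsc_irls(pmin(a$z^2, CHI2_WINSOR), a$n * l2 / M, l2, blocks = blocks)
  u2 <- ldsc_irls(pmin(b$z^2, CHI2_WINSOR), b$n * l2 / M, l2, blocks = blocks)

  y <- pmin(pmax(a$z * b$z, -CHI2_WINSOR), CHI2_WINSOR)
  x <- sqrt(a$n * b$n) * l2 / M
  w <- 1 / (l2 * u1$d * u2$d)
  cross <- wreg_jackknife(y, x, w, blocks)

  gcov <- unname(cross$coef["slope"])
  h2_1 <- unname(u1$fit$coef["slope"]); h2_2 <- unname(u2$fit$coef["slope"])
  rg_raw <- if (h2_1 > 0 && h2_2 > 0) gcov / sqrt(h2_1 * h2_2) else NA_real_
  clamped <- !is.na(rg_raw) && abs(rg_raw) > 1
  rg <- if (is.na(rg_raw)) NA_real_ else max(-1, min(1, rg_raw))

  ## jackknife of rg: recompute the ratio on each leave-one-block-out fit
  se_rg <- NA_real_
  if (!is.na(rg_raw)) {
    loo_rg <- cross$loo[, "slope"] /
      sqrt(pmax(u1$fit$loo[, "slope"], 1e-12) *
             pmax(u2$fit$loo[, "slope"], 1e-12))
    se_rg <- jackknife_se(loo_rg)
  }
  se_gcov <- jackknife_se(cross$loo[, "slope"])
  z_rg <- if (!is.na(rg_raw) && se_rg > 0) rg_raw / se_rg else NA_real_
  structure(list(gcov = gcov,
                 cross_intercept = unname(cross$coef["intercept"]),
                 rg = rg, rg_clamped = clamped,
                 se_gcov = se_gcov, se_rg = se_rg,
                 p_rg = if (is.na(z_rg)) NA_real_ else
                   2 * stats::pnorm(-abs(z_rg)),
                 h2_1 = h2_1, h2_2 = h2_2,
                 n_snps_used = nrow(a)),
            class = "crosstrait_fit")
}

#' @export
print.crosstrait_fit <- function(x, ...) {
  cat(sprintf("<crosstrait_fit> gcov = %.4f (SE %.4f), rg = %s, intercept = %.4f\n",
              x$gcov, x$se_gcov,
              if (is.na(x$rg)) "NA" else sprintf("%.3f (SE %.3f)", x$rg, x$se_rg),
              x$cross_intercept))
  invisible(x)
}

#' Genomic inflation factor
#'
#' Lambda: the median association chi-square (1 df) divided by the null
#' median 0.4549.
#'
#' @param pvals p-values in (0, 1].
#' @return numeric lambda.
#' @export
genomic_inflation <- function(pvals) {
  if (length(pvals) == 0) stop("no p-values supplied")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  chi2 <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}
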