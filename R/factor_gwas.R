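## Multivariate GWAS of the latent factors: per SNP, the genetic covariance
## structure is expanded with the SNP's covariances to every trait and the
## SNP -> factor paths are estimated by weighted least squares with the
## measurement model (Lambda, Psi, Theta) held fixed at the CFA estimates.
##
## With the expanded sampling covariance block-diagonal by construction
## (per-trait sampling variances, zero cross-terms), the WLS estimator
## collapses to a per-SNP generalized regression of trait effects on the
## h2-scaled loading matrix:
##   gamma_hat = (B' Omega B)^-1 B' Omega beta,   B = diag(sqrt(h2)) Lambda*
## with Omega = diag(1/se^2); the sandwich covariance reduces to the bread
## (B' Omega B)^-1. Effects are per-allele on the standardized trait /
## unit-variance factor scale.

#' Expand a covariance structure with one SNP
#'
#' Appends a SNP row/column to the genetic covariance matrix:
#' `var(SNP) = 2 maf (1 - maf)` on the standardized-genotype scale and
#' `cov(SNP, trait) = beta_t * var(SNP)`. The sampling covariance V gains
#' per-trait variances `se_t^2 var(SNP)^2` for the new covariance entries
#' and zero cross-terms; the SNP variance is treated as known.
#'
#' @param gs a `covstruct` (unstandardized: diagonal = h2).
#' @param beta named per-trait SNP effects (per-allele, standardized
#'   trait); must cover every trait in `gs`.
#' @param se matching standard errors.
#' @param maf allele frequency in (0, 0.5].
#' @return a `covstruct` with `k + 1` traits, the SNP appended last as
#'   `"SNP"`.
#' @export
snp_expanded_structure <- function(gs, beta, se, maf) {
  stopifnot(maf > 0, maf <= 0.5)
  miss <- setdiff(gs$traits, names(beta))
  if (length(miss) > 0)
    stop("missing SNP effect for trait(s): ", paste(miss, collapse = ", "))
  beta <- beta[gs$traits]; se <- se[gs$traits]
  k <- length(gs$traits)
  vsnp <- 2 * maf * (1 - maf)

  S2 <- rbind(cbind(gs$S, beta * vsnp), c(beta * vsnp, vsnp))
  traits2 <- c(gs$traits, "SNP")

  k2 <- k + 1
  q2 <- k2 * (k2 + 1) / 2
  idx2 <- vech_index(k2)
  V2 <- matrix(0, q2, q2)
  ## old elements keep their joint sampling covariance
  old <- which(idx2[, 1] <= k & idx2[, 2] <= k)
  V2[old, old] <- gs$V
  ## SNP-trait covariance entries: independent, variance se^2 vsnp^2
  for (t in seq_len(k)) {
    m <- which(idx2[, 1] == k2 & idx2[, 2] == t)
    V2[m, m] <- se[t]^2 * vsnp^2
  }
  I2 <- rbind(cbind(gs$intercepts, 0), 0)
  new_covstruct(traits2, S2, V2, I2, gs$n_blocks,
                standardized = FALSE, M = gs$M)
}

## shared core: gamma-hat and its covariance for one SNP given the
## h2-scaled loading matrix B (p x k), per-trait beta and se
snp_wls <- function(B, beta, se) {
  Om <- 1 / se^2
  A <- crossprod(B, B * Om)
  ok <- diag(A) > 1e-12
  gamma <- rep(NA_real_, ncol(B))
  segm <- rep(NA_real_, ncol(B))
  if (any(ok)) {
    Ai <- tryCatch(solve(A[ok, ok, drop = FALSE]), error = function(e) NULL)
    if (!is.null(Ai)) {
      gamma[ok] <- Ai %*% crossprod(B[, ok, drop = FALSE], beta * Om)
      segm[ok] <- sqrt(pmax(diag(Ai), 0))
    }
  }
  list(beta_f = gamma, se_f = segm)
}

#' SNP-to-factor effects from an expanded structure
#'
#' Estimates the SNP's effect on every latent factor jointly by weighted
#' least squares, with the measurement model fixed at the CFA estimates.
#' A factor with no measured non-zero-loading indicator is returned as
#' `NA` and flagged.
#'
#' @param expanded output of [snp_expanded_structure()].
#' @param spec the fitted `cfa_spec`.
#' @param fit the converged `cfa_fit` providing the measurement model.
#' @return data.frame with one row per factor: `factor, beta_f, se_f, z_f,
#'   pval_f`.
#' @export
fit_snp_to_factors <- function(expanded, spec, fit) {
  if (!isTRUE(fit$converged)) stop("measurement model must be converged")
  traits <- setdiff(expanded$traits, "SNP")
  regions <- spec$regions
  stopifnot(all(regions %in% traits))
  vsnp <- expanded$S["SNP", "SNP"]
  cov_snp <- expanded$S["SNP", regions]
  beta <- cov_snp / vsnp
  idx <- vech_index(length(expanded$traits))
  k2 <- length(expanded$traits)
  se <- vapply(regions, function(t) {
    m <- which(idx[, 1] == k2 & idx[, 2] == match(t, expanded$traits))
    sqrt(expanded$V[m, m]) / vsnp
  }, numeric(1))
  h2 <- diag(expanded$S)[regions]
  B <- sqrt(h2) * fit$loadings_matrix[regions, , drop = FALSE]
  res <- snp_wls(B, beta, se)
  data.frame(factor = spec$factors, beta_f = res$beta_f, se_f = res$se_f,
             z_f = res$beta_f / res$se_f,
             pval_f = 2 * stats::pnorm(-abs(res$beta_f / res$se_f)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multivariate GWAS of the latent factors
#'
#' Applies the per-SNP factor regression across every SNP shared by all
#' trait tables, attaching per-factor genomic inflation factors and an
#' effective sample size `n_eff = 1 / (2 maf (1 - maf) se_f^2)` capped at
#' its 99th percentile (recorded in the output metadata). Deterministic
#' given its inputs.
#'
#' @param tables list of `sumstats` data.frames covering the model regions.
#' @param gs the unstandardized `covstruct` (diagonal = h2) for the same
#'   traits.
#' @param spec the selected `cfa_spec`.
#' @param fit the converged `cfa_fit`.
#' @return object of class `factor_gwas`: data.frame with columns
#'   `snp, chr, bp, a1, a2, maf, factor, beta_f, se_f, z_f, pval_f, n_eff`
#'   and attribute `lambda` (named per-factor genomic inflation).
#' @export
multivariate_gwas <- function(tables, gs, spec, fit) {
  if (!isTRUE(fit$converged)) stop("measurement model must be converged")
  traits <- names(tables) %||%
    vapply(tables, function(t) attr(t, "trait_name"), character(1))
  names(tables) <- traits
  stopifnot(all(spec$regions %in% traits))
  tables <- tables[spec$regions]

  common <- Reduce(intersect, lapply(tables, function(t) t$snp))
  if (length(common) == 0) stop("no SNPs shared across all trait tables")
  first <- as.data.frame(tables[[1]])[match(common, tables[[1]]$snp), ]
  ord <- order(first$chr, first$bp)
  first <- first[ord, ]; common <- common[ord]

  p <- length(spec$regions)
  Beta <- vapply(tables, function(t) t$beta[match(common, t$snp)],
                 numeric(length(common)))
  Se <- vapply(tables, function(t) t$se[match(common, t$snp)],
               numeric(length(common)))
  h2 <- diag(gs$S)[spec$regions]
  if (any(h2 <= 0)) stop("non-positive h2 for model region(s)")
  B <- sqrt(h2) * fit$loadings_matrix[spec$regions, , drop = FALSE]
  k <- ncol(B)

  nsnp <- length(common)
  beta_f <- se_f <- matrix(NA_real_, nsnp, k)
  ## factors with no non-zero-loading indicator are inestimable (left NA)
  ok_f <- colSums(B^2) > 1e-12
  B_all <- B
  B <- B[, ok_f, drop = FALSE]
  kk <- ncol(B)
  ## precompute per-SNP normal-equation pieces:
  ## A_fg(j) = sum_t B_tf B_tg / se_jt^2,  rhs_f(j) = sum_t B_tf beta_jt/se_jt^2
  Om <- 1 / Se^2
  idxk <- vech_index(kk)
  Apair <- vapply(seq_len(nrow(idxk)), function(m)
    drop(Om %*% (B[, idxk[m, 1]] * B[, idxk[m, 2]])), numeric(nsnp))
  Rhs <- (Om * Beta) %*% B
  bsub <- matrix(NA_real_, nsnp, kk)
  ssub <- matrix(NA_real_, nsnp, kk)
  if (kk == 1) {
    bsub[, 1] <- Rhs[, 1] / Apair[, 1]
    ssub[, 1] <- 1 / sqrt(Apair[, 1])
  } else if (kk > 1) {
    for (j in seq_len(nsnp)) {
      A <- unvech(Apair[j, ], kk)
      Ai <- tryCatch(solve(A), error = function(e) NULL)
      if (is.null(Ai)) next
      bsub[j, ] <- Ai %*% Rhs[j, ]
      ssub[j, ] <- sqrt(pmax(diag(Ai), 0))
    }
  }
  beta_f[, ok_f] <- bsub
  se_f[, ok_f] <- ssub
  B <- B_all

  vsnp <- 2 * first$maf * (1 - first$maf)
  out <- do.call(rbind, lapply(seq_len(k), function(f) {
    n_eff <- 1 / (vsnp * se_f[, f]^2)
    cap <- stats::quantile(n_eff, 0.99, na.rm = TRUE, names = FALSE)
    data.frame(snp = common, chr = first$chr, bp = first$bp,
               a1 = first$a1, a2 = first$a2, maf = first$maf,
               factor = spec$factors[f],
               beta_f = beta_f[, f], se_f = se_f[, f],
               z_f = beta_f[, f] / se_f[, f],
               pval_f = 2 * stats::pnorm(-abs(beta_f[, f] / se_f[, f])),
               n_eff = pmin(n_eff, cap),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  lam <- vapply(spec$factors, function(f) {
    pv <- out$pval_f[out$factor == f]
    genomic_inflation(pmax(pv[!is.na(pv)], 1e-300))
  }, numeric(1))
  structure(out, class = c("factor_gwas", "data.frame"),
            lambda = lam, n_eff_cap = "99th percentile")
}

#' Convert one factor's GWAS to a summary-statistics table
#'
#' Packages the factor associations as a `sumstats` table (Z, per-allele
#' beta/SE, effective N) for downstream cross-trait LDSC.
#'
#' @param gwas a `factor_gwas`.
#' @param factor factor name.
#' @return a `sumstats` data.frame.
#' @export
factor_gwas_to_sumstats <- function(gwas, factor) {
  sub <- as.data.frame(gwas)[gwas$factor == factor, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown factor: ", factor)
  new_sumstats(data.frame(snp = sub$snp, chr = sub$chr, bp = sub$bp,
                          a1 = sub$a1, a2 = sub$a2, maf = sub$maf,
                          beta = sub$beta_f, se = sub$se_f, z = sub$z_f,
                          p = sub$pval_f, n = sub$n_eff, info = 1),
               trait_name = factor)
}

#' Greedy distance-based locus clumping
#'
#' Takes the most significant remaining genome-wide-significant SNP as a
#' lead, absorbs all GWS SNPs within `window` base pairs on the same
#' chromosome, and repeats; locus spans are padded by the window
#' (`min bp - window` to `max bp + window`) and overlapping spans merged,
#' so the loci coincide with the merged union of per-SNP windows. Rows
#' from several factors are pooled by SNP (minimum p across factors)
#' before clumping.
#'
#' @param gwas a `factor_gwas` (or any data.frame with `snp, chr, bp` and a
#'   p-value column `pval_f`).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param window clumping half-window in base pairs (default 250000).
#' @return data.frame with one row per locus: `lead_snp, chr, start, end,
#'   span, n_snps, min_p`.
#' @export
clump_loci <- function(gwas, p_threshold = 5e-8, window = 250000) {
  df <- as.data.frame(gwas)[, c("snp", "chr", "bp", "pval_f")]
  df <- df[!is.na(df$pval_f) & df$pval_f < p_threshold, , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(lead_snp = character(0), chr = numeric(0),
                      start = numeric(0), end = numeric(0), span = numeric(0),
                      n_snps = integer(0), min_p = numeric(0)))
  ## pool across factors: per SNP keep the smallest p
  df <- df[order(df$pval_f), ]
  df <- df[!duplicated(df$snp), , drop = FALSE]

  loci <- list()
  remaining <- df
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    inwin <- remaining$chr == lead$chr & abs(remaining$bp - lead$bp) <= window
    members <- remaining[inwin, , drop = FALSE]
    loci[[length(loci) + 1]] <-
      data.frame(lead_snp = lead$snp, chr = lead$chr,
                 start = max(min(members$bp) - window, 1),
                 end = max(members$bp) + window,
                 n_snps = nrow(members), min_p = lead$pval_f,
                 stringsAsFactors = FALSE)
    remaining <- remaining[!inwin, , drop = FALSE]
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  ## merge overlapping spans on the same chromosome
  merged <- list()
  cur <- out[1, ]
  if (nrow(out) > 1) for (i in 2:nrow(out)) {
    nxt <- out[i, ]
    if (nxt$chr == cur$chr && nxt$start <= cur$end) {
      cur$end <- max(cur$end, nxt$end)
      cur$n_snps <- cur$n_snps + nxt$n_snps
      if (nxt$min_p < cur$min_p) {
        cur$min_p <- nxt$min_p; cur$lead_snp <- nxt$lead_snp
      }
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- do.call(rbind, merged)
  out$span <- out$end - out$start
  rownames(out) <- NULL
  out[c("lead_snp", "chr", "start", "end", "span", "n_snps", "min_p")]
}
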