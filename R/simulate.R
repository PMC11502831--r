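## Synthetic GWAS summary statistics under a planted factor model, with
## LDSC-consistent statistical structure: per SNP j the trait Z-scores are
## drawn so that E[Z_t Z_u] = intercept_tu + sqrt(N_t N_u) Sigma_g[t,u] l_j / M,
## the model LD score regression assumes. The planted genetic covariance is
## Sigma_g = D^{1/2} (Lambda Psi Lambda' + Theta) D^{1/2} with the loading
## matrix expressed in the correlation metric and D = diag(h2).

#' Truth parameters for the synthetic study
#'
#' Defaults mirror the package's desk-scale reference conditions: 8 traits,
#' 2 correlated factors (loading blocks 0.7 and 0.6, factor correlation
#' 0.7), SNP heritability 0.25, N = 50000, M = 50000.
#'
#' @param p trait count.
#' @param k factor count.
#' @param loadings p x k loading matrix in the correlation metric; default
#'   a two-block pattern (first half of traits at 0.7 on F1, second half
#'   at 0.6 on F2).
#' @param psi k x k factor correlation matrix; default off-diagonal 0.7.
#' @param h2 per-trait SNP heritability (scalar recycled).
#' @param n per-trait GWAS sample size (scalar recycled).
#' @param m SNP count.
#' @param n_ld_blocks LD blocks (LD scores constant within a block).
#' @param intercepts p x p sample-overlap intercept matrix (default
#'   identity: no confounding, no overlap).
#' @param causal optional data.frame with columns `snp_index, factor,
#'   gamma`: large-effect causal SNPs acting through a factor, `gamma` the
#'   per-allele effect on the unit-variance factor.
#' @param seed RNG seed.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(p = 8, k = 2, loadings = NULL, psi = NULL,
                         h2 = 0.25, n = 50000, m = 50000, n_ld_blocks = 40,
                         intercepts = NULL, causal = NULL, seed = 1) {
  if (is.null(loadings)) {
    loadings <- matrix(0, p, k)
    half <- ceiling(p / 2)
    loadings[seq_len(half), 1] <- 0.7
    if (k >= 2) loadings[(half + 1):p, 2] <- 0.6
  }
  if (is.null(psi)) {
    psi <- diag(k)
    psi[psi == 0] <- 0.7
  }
  stopifnot(nrow(loadings) == p, ncol(loadings) == k,
            all(abs(diag(psi) - 1) < 1e-12), m >= n_ld_blocks)
  theta <- 1 - diag(loadings %*% psi %*% t(loadings))
  if (any(theta <= 0))
    stop("loadings imply communality >= 1; reduce them")
  h2 <- rep_len(h2, p)
  n <- rep_len(n, p)
  if (is.null(intercepts)) intercepts <- diag(p)
  if (!is.null(causal))
    stopifnot(all(c("snp_index", "factor", "gamma") %in% names(causal)))
  traits <- sprintf("trait%02d", seq_len(p))
  sigma_star <- loadings %*% psi %*% t(loadings) + diag(theta)
  sigma_g <- sqrt(h2) * t(sqrt(h2) * sigma_star)
  dimnames(sigma_g) <- list(traits, traits)
  structure(list(p = p, k = k, loadings = loadings, psi = psi,
                 theta = theta, h2 = h2, n = n, m = m,
                 n_ld_blocks = n_ld_blocks, intercepts = intercepts,
                 causal = causal, seed = seed, traits = traits,
                 sigma_star = sigma_star, sigma_g = sigma_g),
            class = "truth_params")
}

#' Simulate an LD-score table
#'
#' SNPs are assigned to the 22 autosomes round-robin with 1-based
#' positions, then sorted by (chromosome, position). LD scores are drawn
#' from a right-skewed log-normal (median 10) and held constant within
#' each of `n_blocks` contiguous blocks; `n_blocks = 1` gives a single
#' shared LD score. Reproducible given `seed`.
#'
#' @param m SNP count.
#' @param n_blocks LD block count.
#' @param seed RNG seed.
#' @return an `ldscores` data.frame with attributes `M` and `blocks` (the
#'   per-SNP block index).
#' @export
simulate_ld <- function(m, n_blocks, seed = 1) {
  if (m < n_blocks) stop("m must be at least n_blocks")
  i <- seq_len(m)
  df <- data.frame(chr = (i - 1) %% 22 + 1,
                   snp = sprintf("rs%06d", i),
                   bp = ((i - 1) %/% 22 + 1) * 10000)
  df <- df[order(df$chr, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  blocks <- jackknife_blocks(m, max(n_blocks, 2))
  if (n_blocks == 1) blocks <- rep(1L, m)
  lvals <- with_seed(seed, stats::rlnorm(n_blocks, meanlog = log(10),
                                         sdlog = 0.5))
  df$l2 <- lvals[blocks]
  new_ldscores(df, M = m, blocks = blocks)
}

#' Simulate GWAS summary statistics under the planted factor model
#'
#' Two generative modes. `"covariance"` (default): per SNP the p-vector of
#' Z-scores is multivariate normal with covariance
#' `intercepts + sqrt(N N') * Sigma_g * l_j / M`, exactly the second-moment
#' structure LDSC fits; used for all covariance/factor-structure testing.
#' `"causal"`: explicit per-SNP effects — dense polygenic factor effects
#' `gamma_j ~ MVN(0, Psi l_j / M)` plus the listed large-effect causal SNPs
#' and trait-specific residual effects — mapped to trait effects through
#' the loading matrix; markers are unlinked but effect variances scale
#' with the LD score so the LDSC moment identity still holds; used for
#' per-SNP factor-GWAS recovery and power testing. Betas and SEs are
#' back-filled from Z, N and the standardized genotype variance
#' `2 maf (1 - maf)`.
#'
#' @param truth a `truth_params` object.
#' @param mode `"covariance"` or `"causal"`.
#' @param background in causal mode, draw the dense polygenic background
#'   effects (default TRUE); `FALSE` leaves only the listed causal SNPs,
#'   the regime in which the normal-approximation power formula applies.
#' @return object of class `simulated_study`: list with `tables` (named
#'   list of `sumstats`), `ld`, `truth`, `manifest`.
#' @export
simulate_sumstats <- function(truth, mode = c("covariance", "causal"),
                              background = TRUE) {
  mode <- match.arg(mode)
  ld <- simulate_ld(truth$m, truth$n_ld_blocks, truth$seed)
  blocks <- attr(ld, "blocks")
  p <- truth$p
  m <- truth$m

  Z <- with_seed(truth$seed + 1L, {
    maf <- stats::runif(m, 0.05, 0.5)
    if (mode == "covariance") {
      Zm <- matrix(NA_real_, m, p)
      scale_nn <- tcrossprod(sqrt(truth$n))
      for (b in unique(blocks)) {
        rows <- which(blocks == b)
        C <- truth$intercepts + scale_nn * truth$sigma_g * ld$l2[rows[1]] / m
        ev <- eigen(C, symmetric = TRUE)
        if (min(ev$values) < -1e-8)
          stop("non-PSD per-SNP covariance in block ", b,
               " (inconsistent truth parameters)")
        rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
        Zm[rows, ] <- matrix(stats::rnorm(length(rows) * p),
                             length(rows), p) %*% rt
      }
      list(Z = Zm, maf = maf)
    } else {
      ## explicit independent per-SNP effects whose variance scales with the
      ## LD score, reproducing E[chi2] = 1 + N h2 l/M without physical
      ## smearing (markers stay unlinked)
      lscale <- if (background) sqrt(ld$l2 / m) else 0
      gam <- (matrix(stats::rnorm(m * truth$k), m, truth$k) %*%
                chol(truth$psi)) * lscale
      if (!is.null(truth$causal)) {
        sdg <- sqrt(2 * maf * (1 - maf))
        for (r in seq_len(nrow(truth$causal))) {
          j <- truth$causal$snp_index[r]
          f <- truth$causal$factor[r]
          gam[j, f] <- gam[j, f] + truth$causal$gamma[r] * sdg[j]
        }
      }
      delta <- (matrix(stats::rnorm(m * p), m, p) %*%
                  diag(sqrt(truth$theta), p)) * lscale
      b_std <- (gam %*% t(truth$loadings) + delta) %*%
        diag(sqrt(truth$h2), p)
      noise <- matrix(stats::rnorm(m * p), m, p) %*%
        chol(truth$intercepts)
      list(Z = sweep(b_std, 2, sqrt(truth$n), `*`) + noise, maf = maf)
    }
  })
  maf <- Z$maf
  Zm <- Z$Z

  sdg <- sqrt(2 * maf * (1 - maf))
  tables <- lapply(seq_len(p), function(t) {
    se <- 1 / (sqrt(truth$n[t]) * sdg)
    new_sumstats(data.frame(snp = ld$snp, chr = ld$chr, bp = ld$bp,
                            a1 = "A", a2 = "G", maf = maf,
                            beta = Zm[, t] * se, se = se, z = Zm[, t],
                            p = 2 * stats::pnorm(-abs(Zm[, t])),
                            n = truth$n[t], info = 1),
                 trait_name = truth$traits[t],
                 provenance = sprintf("simulated (%s mode, seed %d)",
                                      mode, truth$seed))
  })
  names(tables) <- truth$traits

  manifest <- list(mode = mode, p = p, k = truth$k, m = m,
                   n = as.numeric(truth$n), h2 = as.numeric(truth$h2),
                   n_ld_blocks = truth$n_ld_blocks, seed = truth$seed,
                   loadings = apply(truth$loadings, 1, as.numeric,
                                    simplify = FALSE),
                   psi = apply(truth$psi, 1, as.numeric, simplify = FALSE),
                   theta = as.numeric(truth$theta),
                   causal = if (is.null(truth$causal)) NULL else
                     as.list(truth$causal))
  structure(list(tables = tables, ld = ld, truth = truth,
                 manifest = manifest),
            class = "simulated_study")
}

#' Write / read the simulation manifest
#'
#' The manifest records every planted value as YAML and round-trips.
#'
#' @param study a `simulated_study` (or its `manifest` list).
#' @param path file path.
#' @return `path` (write) or the manifest list (read).
#' @export
write_manifest <- function(study, path) {
  manifest <- if (inherits(study, "simulated_study")) study$manifest else study
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)

#' Region-set fixtures
#'
#' Reproducible named region sets over a synthetic universe, standing in
#' for a cortical parcellation and its reference schemes. Planted overlaps
#' between designated pairs allow exact downstream Dice values.
#'
#' @param universe_size number of regions (named `r01`, `r02`, ...).
#' @param gibn_sizes named integer vector: factor-set sizes.
#' @param ref_sizes named integer vector: reference-set sizes.
#' @param seed RNG seed.
#' @param planted optional list of `list(gibn =, ref =, shared =)` entries:
#'   the reference is rebuilt to share exactly `shared` regions with the
#'   named factor set.
#' @return list with `universe`, `gibns`, `references` (lists of
#'   `region_set`s).
#' @export
make_region_fixtures <- function(universe_size, gibn_sizes, ref_sizes,
                                 seed = 1, planted = NULL) {
  stopifnot(all(gibn_sizes <= universe_size), all(ref_sizes <= universe_size))
  universe <- sprintf("r%02d", seq_len(universe_size))
  with_seed(seed, {
    gibns <- lapply(names(gibn_sizes), function(nm)
      region_set(nm, sample(universe, gibn_sizes[[nm]]), universe))
    names(gibns) <- names(gibn_sizes)
    refs <- lapply(names(ref_sizes), function(nm)
      region_set(nm, sample(universe, ref_sizes[[nm]]), universe))
    names(refs) <- names(ref_sizes)
    for (pl in planted) {
      g <- gibns[[pl$gibn]]
      size <- ref_sizes[[pl$ref]]
      stopifnot(pl$shared <= length(g$members),
                size - pl$shared <= universe_size - length(g$members))
      inside <- sample(g$members, pl$shared)
      outside <- sample(setdiff(universe, g$members), size - pl$shared)
      refs[[pl$ref]] <- region_set(pl$ref, c(inside, outside), universe)
    }
    list(universe = universe, gibns = gibns, references = refs)
  })
}
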