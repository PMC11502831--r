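test_that("SNP expansion follows the genotype-variance formulas", {
  gs <- shared_covstruct()
  k <- length(gs$traits)
  beta <- setNames(rep(0, k), gs$traits)
  se <- setNames(rep(0.01, k), gs$traits)
  ex <- snp_expanded_structure(gs, beta, se, maf = 0.5)
  expect_equal(ex$S["SNP", "SNP"], 0.5)
  expect_equal(unname(ex$S["SNP", gs$traits]), rep(0, k))

  beta2 <- setNames(seq(0.01, 0.08, by = 0.01), gs$traits)
  ex2 <- snp_expanded_structure(gs, beta2, se, maf = 0.25)
  vsnp <- 2 * 0.25 * 0.75
  expect_equal(unname(ex2$S["SNP", gs$traits]), unname(beta2) * vsnp)
  ## expanded V: per-trait sampling variances on the new entries
  idx <- vech_index(k + 1)
  m1 <- which(idx[, 1] == k + 1 & idx[, 2] == 1)
  expect_equal(ex2$V[m1, m1], 0.01^2 * vsnp^2)
  expect_error(snp_expanded_structure(gs, beta2[-1], se, 0.25), "missing")
})

test_that("expanded covariances match an individual-level simulation", {
  ## oracle: simulate genotypes and phenotypes directly and compare the
  ## empirical cov(genotype, trait) with the formula 2 maf (1-maf) beta
  set.seed(11)
  n <- 50000; maf <- 0.3; beta_std <- 0.04
  g <- rbinom(n, 2, maf)
  y <- beta_std * g + rnorm(n)
  emp <- cov(g, y)
  mc_se <- sqrt(var(g * y) / n)
  expect_lt(abs(emp - beta_std * 2 * maf * (1 - maf)), 3 * mc_se + 1e-3)
})

test_that("a unit-loading single-indicator factor passes the trait beta through", {
  S <- matrix(1, 1, 1, dimnames = list("t1", "t1"))
  gs <- gibnet:::new_covstruct("t1", S, matrix(1e-6, 1, 1), diag(1),
                               n_blocks = 50)
  spec <- structure(list(regions = "t1", factors = "F1",
                         loadings = data.frame(region = "t1", factor = "F1"),
                         psi_free = FALSE, start = NULL),
                    class = "cfa_spec")
  fit <- structure(list(converged = TRUE,
                        loadings_matrix = matrix(1, 1, 1,
                                                 dimnames = list("t1", "F1")),
                        psi_matrix = diag(1), theta_resid = 0),
                   class = "cfa_fit")
  ex <- snp_expanded_structure(gs, c(t1 = 0.031), c(t1 = 0.01), maf = 0.2)
  res <- fit_snp_to_factors(ex, spec, fit)
  expect_equal(res$beta_f, 0.031, tolerance = 1e-8)
  expect_equal(res$se_f, 0.01, tolerance = 1e-8)

  ## zero covariance with every trait -> zero factor effect
  ex0 <- snp_expanded_structure(gs, c(t1 = 0), c(t1 = 0.01), maf = 0.2)
  expect_equal(fit_snp_to_factors(ex0, spec, fit)$beta_f, 0)
})

test_that("causal effects through a factor are recovered at the planted size", {
  caus <- data.frame(snp_index = seq(50, 5000, by = 50), factor = 1,
                     gamma = 0.05)
  tp <- truth_params(m = 20000, n_ld_blocks = 20, seed = 7, causal = caus)
  st <- simulate_sumstats(tp, mode = "causal")
  gs <- build_covariance_structure(st$tables, st$ld, n_blocks = 100)
  std <- smooth_structure(standardize_structure(gs))
  fit <- fit_cfa(true_spec(), std)
  expect_true(fit$converged)
  gw <- multivariate_gwas(st$tables, gs, true_spec(), fit)
  sub <- as.data.frame(gw)[gw$factor == "F1", ]
  causal_ids <- st$ld$snp[caus$snp_index]
  est <- sub$beta_f[match(causal_ids, sub$snp)]
  expect_equal(mean(est), 0.05, tolerance = 0.01)
  ## the other factor picks up only the correlated share
  sub2 <- as.data.frame(gw)[gw$factor == "F2", ]
  est2 <- sub2$beta_f[match(causal_ids, sub2$snp)]
  expect_lt(mean(est2), mean(est))
})

test_that("factor Z is monotone in trait Z for duplicated input traits", {
  st <- shared_study()
  t1 <- st$tables[[1]]
  gs <- build_covariance_structure(list(a = t1, b = t1), st$ld,
                                   n_blocks = 100)
  spec <- cfa_spec(data.frame(region = c("a", "b"), factor = "F1"))
  fit <- structure(list(converged = TRUE,
                        loadings_matrix = matrix(c(0.9, 0.9), 2, 1,
                                                 dimnames = list(c("a", "b"),
                                                                 "F1")),
                        psi_matrix = diag(1), theta_resid = c(0.19, 0.19)),
                   class = "cfa_fit")
  gw <- multivariate_gwas(list(a = t1, b = t1), gs, spec, fit)
  zf <- gw$z_f[match(t1$snp, gw$snp)]
  expect_gt(cor(zf, t1$z, method = "spearman", use = "complete.obs"), 0.99)
})

test_that("results for a factor ignore non-indicator traits", {
  st <- shared_study()
  std <- shared_std()
  gs <- shared_covstruct()
  fit <- fit_cfa(true_spec(), std)
  gw_full <- multivariate_gwas(st$tables, gs, true_spec(), fit)
  ## restricting the input tables to F1's indicators leaves F1 unchanged
  spec1 <- cfa_spec(data.frame(region = sprintf("trait%02d", 1:4),
                               factor = "F1"))
  fit1 <- fit
  fit1$spec <- spec1
  fit1$loadings_matrix <- fit$loadings_matrix[1:4, 1, drop = FALSE]
  fit1$psi_matrix <- diag(1)
  fit1$theta_resid <- fit$theta_resid[1:4]
  gw_f1 <- multivariate_gwas(st$tables[1:4], gs, spec1, fit1)
  a <- gw_full$beta_f[gw_full$factor == "F1"]
  b <- gw_f1$beta_f[gw_f1$factor == "F1"]
  expect_equal(a[match(gw_f1$snp[gw_f1$factor == "F1"],
                       gw_full$snp[gw_full$factor == "F1"])],
               b, tolerance = 1e-10)
})

test_that("locus clumping follows the window rule and merges overlaps", {
  df <- data.frame(snp = c("s1", "s2"), chr = 1, bp = c(1e5, 2e5),
                   pval_f = c(1e-9, 1e-10))
  out <- clump_loci(df, window = 250000)
  expect_equal(nrow(out), 1)
  expect_equal(out$lead_snp, "s2")
  expect_equal(nrow(clump_loci(data.frame(snp = "s", chr = 1, bp = 1,
                                          pval_f = 1e-6))), 0)
})

test_that("clumping agrees with an interval-merging oracle on random inputs", {
  oracle_count <- function(bp, chr, window) {
    ## independent oracle: union of +-window intervals around GWS SNPs,
    ## merged per chromosome
    n_loci <- 0
    for (cc in unique(chr)) {
      x <- sort(bp[chr == cc])
      ivs <- cbind(x - window, x + window)
      n <- 1
      hi <- ivs[1, 2]
      for (i in seq_len(nrow(ivs))[-1]) {
        if (ivs[i, 1] > hi) { n <- n + 1; hi <- ivs[i, 2] }
        else hi <- max(hi, ivs[i, 2])
      }
      n_loci <- n_loci + n
    }
    n_loci
  }
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(1:25, 1)
    df <- data.frame(snp = paste0("s", 1:n),
                     chr = sample(1:3, n, replace = TRUE),
                     bp = sample(1:2e6, n),
                     pval_f = 10^-runif(n, 8, 12))
    window <- sample(c(5e4, 1e5, 2.5e5), 1)
    got <- nrow(clump_loci(df, window = window))
    want <- oracle_count(df$bp, df$chr, window)
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("locus count is non-increasing in the window size", {
  set.seed(8)
  df <- data.frame(snp = paste0("s", 1:50), chr = sample(1:2, 50, TRUE),
                   bp = sample(1:5e6, 50), pval_f = 10^-runif(50, 8, 12))
  counts <- vapply(c(1e4, 1e5, 5e5, 2e6), function(w)
    nrow(clump_loci(df, window = w)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
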