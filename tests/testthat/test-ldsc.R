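test_that("flat chi-square gives h2 = 0 and intercept = 1", {
  ld <- simulate_ld(2000, 10, seed = 1)
  tab <- make_sumstats(2000, chr = ld$chr, z = rep(1, 2000))
  tab$snp <- ld$snp; tab$bp <- ld$bp
  tab <- gibnet:::new_sumstats(as.data.frame(tab))
  fit <- univariate_ldsc(tab, ld, n_blocks = 50)
  expect_lt(abs(fit$h2), 1e-8)
  expect_lt(abs(fit$intercept - 1), 1e-8)
  expect_error(univariate_ldsc(make_sumstats(50), ld), "too few")
})

test_that("univariate LDSC recovers planted h2 and intercept", {
  ## ldsc-mode simulation, 8 LD blocks: h2-hat within 3 jackknife SEs
  hits <- 0; h2s <- ints <- numeric(0)
  for (s in 1:10) {
    tp <- truth_params(p = 2, k = 1,
                       loadings = matrix(c(0.7, 0.7), 2, 1),
                       h2 = 0.4, m = 50000, n = 50000, n_ld_blocks = 8,
                       seed = 100 + s)
    st <- simulate_sumstats(tp)
    fit <- univariate_ldsc(st$tables[[1]], st$ld, n_blocks = 200)
    hits <- hits + (abs(fit$h2 - 0.4) < 3 * fit$se_h2)
    h2s <- c(h2s, fit$h2); ints <- c(ints, fit$intercept)
  }
  expect_gte(hits, 9)
  expect_lt(abs(mean(h2s) - 0.4), 0.02)
  expect_lt(abs(mean(ints) - 1), 0.02)
})

test_that("cross-trait LDSC honors self-correlation and sign antisymmetry", {
  st <- shared_study()
  t1 <- st$tables[[1]]
  fit <- bivariate_ldsc(t1, t1, st$ld, n_blocks = 100)
  expect_equal(fit$rg, 1, tolerance = 1e-6)
  neg <- t1; neg$z <- -neg$z; neg$beta <- -neg$beta
  fit2 <- bivariate_ldsc(t1, neg, st$ld, n_blocks = 100)
  expect_equal(fit2$rg, -1, tolerance = 1e-6)
  ## symmetry in the trait order
  t2 <- st$tables[[5]]
  a <- bivariate_ldsc(t1, t2, st$ld, n_blocks = 100)
  b <- bivariate_ldsc(t2, t1, st$ld, n_blocks = 100)
  expect_equal(a$gcov, b$gcov, tolerance = 1e-10)
  expect_equal(a$rg, b$rg, tolerance = 1e-10)
})

test_that("null traits give rg estimates consistent with zero", {
  ## two independent traits (no shared factor): planted rg = 0
  ok <- 0
  for (s in 1:20) {
    tp <- truth_params(p = 2, k = 2,
                       loadings = diag(c(0.7, 0.7)),
                       psi = diag(2), m = 20000, n = 20000,
                       n_ld_blocks = 20, seed = 200 + s)
    st <- simulate_sumstats(tp)
    fit <- bivariate_ldsc(st$tables[[1]], st$tables[[2]], st$ld,
                          n_blocks = 100)
    ok <- ok + (abs(fit$rg) < 3 * fit$se_rg)
  }
  expect_gte(ok, 17)  # ~95% coverage, allow binomial slack at n = 20
})

test_that("covariance structure has consistent dimensions and symmetry", {
  gs <- shared_covstruct()
  k <- length(gs$traits)
  expect_equal(dim(gs$S), c(k, k))
  expect_equal(dim(gs$V), rep(k * (k + 1) / 2, 2))
  expect_true(isSymmetric(gs$S))
  expect_true(isSymmetric(gs$V, tol = 1e-10))
  expect_true(all(diag(gs$V) >= 0))

  ## duplicated trait: identical rows/columns in S
  st <- shared_study()
  dup <- list(a = st$tables[[1]], b = st$tables[[1]], c = st$tables[[2]])
  gsd <- build_covariance_structure(dup, st$ld, n_blocks = 100)
  expect_equal(gsd$S["a", "c"], gsd$S["b", "c"], tolerance = 1e-10)
  expect_equal(gsd$S["a", "a"], gsd$S["b", "b"], tolerance = 1e-10)
})

test_that("V diagonal matches the univariate jackknife variance", {
  st <- shared_study()
  gs <- shared_covstruct()
  fit <- univariate_ldsc(st$tables[[1]], st$ld, n_blocks = 200)
  expect_equal(gs$V[1, 1], fit$se_h2^2, tolerance = 0.1)
})

test_that("jackknife V is stable in the block count", {
  st <- shared_study()
  g100 <- build_covariance_structure(st$tables[1:3], st$ld, n_blocks = 100)
  g200 <- build_covariance_structure(st$tables[1:3], st$ld, n_blocks = 200)
  ratio <- diag(g100$V) / diag(g200$V)
  expect_true(all(ratio > 1 / 1.5 & ratio < 1.5))
})

test_that("standardization rescales S and V consistently and is idempotent", {
  ## hand case: diag (4, 1), covariance 1 -> correlation 0.5
  gs <- gibnet:::new_covstruct(c("a", "b"),
                               S = matrix(c(4, 1, 1, 1), 2),
                               V = diag(c(0.1, 0.05, 0.02)),
                               intercepts = diag(2), n_blocks = 50)
  std <- standardize_structure(gs)
  expect_equal(std$S[1, 2], 0.5)
  expect_equal(diag(std$S), c(a = 1, b = 1))
  twice <- standardize_structure(std)
  expect_equal(twice$S, std$S, tolerance = 1e-10)
  expect_equal(twice$V, std$V, tolerance = 1e-10)

  bad <- gs; bad$S[2, 2] <- -0.1
  expect_error(standardize_structure(bad), "b")
})

test_that("delta-method V agrees with a direct jackknife of the correlation", {
  st <- shared_study()
  gs <- build_covariance_structure(st$tables[1:3], st$ld, n_blocks = 200)
  std <- standardize_structure(gs)
  ## brute-force oracle: jackknife the standardized statistic directly by
  ## recomputing r12 on each leave-one-block-out covariance estimate
  tabs <- lapply(st$tables[1:3], function(t) t)
  common <- Reduce(intersect, c(lapply(tabs, function(t) t$snp),
                                list(st$ld$snp)))
  l2 <- pmax(st$ld$l2[match(common, st$ld$snp)], 1)
  Z <- vapply(tabs, function(t) t$z[match(common, t$snp)],
              numeric(length(common)))
  N <- vapply(tabs, function(t) t$n[match(common, t$snp)],
              numeric(length(common)))
  M <- attr(st$ld, "M")
  blocks <- gibnet:::jackknife_blocks(length(common), 200)
  u1 <- gibnet:::ldsc_irls(pmin(Z[, 1]^2, 80), N[, 1] * l2 / M, l2,
                           blocks = blocks)
  u2 <- gibnet:::ldsc_irls(pmin(Z[, 2]^2, 80), N[, 2] * l2 / M, l2,
                           blocks = blocks)
  cr <- gibnet:::wreg_jackknife(pmin(pmax(Z[, 1] * Z[, 2], -80), 80),
                                sqrt(N[, 1] * N[, 2]) * l2 / M,
                                1 / (l2 * u1$d * u2$d), blocks)
  loo_r <- cr$loo[, "slope"] /
    sqrt(u1$fit$loo[, "slope"] * u2$fit$loo[, "slope"])
  se_direct <- gibnet:::jackknife_se(loo_r)
  ## vech order for k=3: (1,1),(2,1),(3,1),(2,2),... -> r12 is element 2
  expect_equal(sqrt(std$V[2, 2]), se_direct, tolerance = 0.15)
})

test_that("PSD smoothing clips eigenvalues and preserves PSD inputs", {
  R <- diag(3)
  expect_identical(smooth_to_psd(R)[1, 1], 1)
  expect_equal(attr(smooth_to_psd(R), "max_change"), 0)

  ## plant a negative eigenvalue
  e <- eigen(matrix(c(1, .9, .9, .9, 1, .9, .9, .9, 1), 3))
  vals <- c(2.8, 0.25, -0.05)
  M <- e$vectors %*% diag(vals) %*% t(e$vectors)
  M <- (M + t(M)) / 2
  sm <- smooth_to_psd(M)
  expect_gte(min(eigen(sm)$values), 1e-6 - 1e-12)
  ## independent clip-reconstruct oracle
  oracle <- e$vectors %*% diag(pmax(vals, 1e-6)) %*% t(e$vectors)
  oracle <- stats::cov2cor((oracle + t(oracle)) / 2)
  expect_equal(as.vector(sm), as.vector(oracle), tolerance = 1e-8)
  expect_gt(attr(sm, "max_change"), 0)
})

test_that("genomic inflation matches its definition and scales correctly", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1, tolerance = 1e-3)
  set.seed(7)
  p_null <- runif(100000)
  expect_true(abs(genomic_inflation(p_null) - 1) < 0.02)
  chi <- qchisq(p_null, 1, lower.tail = FALSE) * 1.1
  p_inf <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_inf), 1.1, tolerance = 0.01)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
})
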