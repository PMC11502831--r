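# helper: an exact low-noise structure S = Lambda Psi Lambda' + Theta
exact_structure <- function(lam = c(0.8, 0.7, 0.6, 0.75, 0.65, 0.6),
                            psi12 = 0.5, vdiag = 1e-8) {
  Lam <- matrix(0, 6, 2)
  Lam[1:3, 1] <- lam[1:3]; Lam[4:6, 2] <- lam[4:6]
  Psi <- matrix(c(1, psi12, psi12, 1), 2)
  Th <- 1 - diag(Lam %*% Psi %*% t(Lam))
  S <- Lam %*% Psi %*% t(Lam) + diag(Th)
  traits <- paste0("r", 1:6)
  dimnames(S) <- list(traits, traits)
  gs <- gibnet:::new_covstruct(traits, S, diag(vdiag, 21), diag(6),
                               n_blocks = 50, standardized = TRUE)
  list(gs = gs, Lam = Lam, Psi = Psi, Th = Th)
}

test_that("spec building applies the cutoff, cross-loadings and factor rules", {
  L <- rbind(c(0.29, 0.00), c(0.31, 0.00), c(0.62, 0.00),
             c(0.60, 0.45), c(0.00, 0.70), c(0.00, 0.72))
  dimnames(L) <- list(paste0("r", 1:6), c("F1", "F2"))
  efa <- structure(list(loadings = L, converged = TRUE), class = "efa_result")
  spec <- build_cfa_spec(efa, 0.3)
  ld <- spec$loadings
  expect_false(any(ld$region == "r1"))              # 0.29 excluded
  expect_true(any(ld$region == "r2"))               # 0.31 included
  expect_equal(sum(ld$region == "r4"), 2)           # cross-loading kept

  ## a factor left with a single indicator is removed with its region
  L2 <- rbind(c(0.6, 0), c(0.7, 0), c(0, 0.8), c(0.05, 0.1))
  dimnames(L2) <- list(paste0("r", 1:4), c("F1", "F2"))
  efa2 <- structure(list(loadings = L2, converged = TRUE),
                    class = "efa_result")
  spec2 <- build_cfa_spec(efa2, 0.3)
  expect_equal(length(spec2$factors), 1)
  expect_setequal(spec2$regions, c("r1", "r2"))
  expect_error(build_cfa_spec(efa2, 0.9), "no viable spec")
})

test_that("DWLS recovers an exact factor structure with perfect fit", {
  ex <- exact_structure()
  spec <- cfa_spec(data.frame(region = paste0("r", 1:6),
                              factor = rep(c("F1", "F2"), each = 3)))
  fit <- fit_cfa(spec, ex$gs)
  expect_true(fit$converged)
  lam_hat <- fit$estimates[grep("^lambda", names(fit$estimates))]
  expect_equal(unname(lam_hat), c(0.8, 0.7, 0.6, 0.75, 0.65, 0.6),
               tolerance = 1e-4)
  expect_equal(unname(fit$estimates["psi:F1:F2"]), 0.5, tolerance = 1e-4)
  expect_lt(fit$SRMR, 1e-6)
  expect_equal(fit$CFI, 1)
  expect_lt(fit$chi2, 1e-4)
})

test_that("full-pipeline CFA recovers planted loadings on the even parity", {
  fit <- fit_cfa(true_spec(), shared_std("even"))
  expect_true(fit$converged)
  truth <- c(rep(0.7, 4), rep(0.6, 4))
  lam_hat <- fit$estimates[grep("^lambda", names(fit$estimates))]
  expect_true(all(abs(lam_hat - truth) < 0.1))
  expect_equal(unname(fit$estimates["psi:F1:F2"]), 0.7, tolerance = 0.15)
  expect_lt(fit$SRMR, 0.05)
  expect_gt(fit$CFI, 0.95)
})

test_that("an ill-conditioned specification reports non-convergence", {
  ex <- exact_structure()
  ## two factors loading identically on the same two regions
  spec <- cfa_spec(data.frame(region = c("r1", "r2", "r1", "r2"),
                              factor = c("F1", "F1", "F2", "F2")))
  fit <- fit_cfa(spec, ex$gs)
  expect_s3_class(fit, "cfa_fit")
  expect_false(isTRUE(fit$converged) && is.null(fit$diagnostic))
})

test_that("fit indices follow their formulas", {
  expect_equal(fit_indices(10, 4, 5, 100, 10, rep(0, 10))$AIC, 20)
  expect_equal(fit_indices(4, 4, 5, 100, 10, rep(0, 10))$CFI, 1)
  expect_equal(fit_indices(10, 4, 5, 100, 10, rep(0, 10))$SRMR, 0)
  ## saturated baseline: denominator zero -> CFI = 1 by convention
  expect_equal(fit_indices(3, 4, 5, 2, 10, rep(0.1, 4))$CFI, 1)
  expect_equal(fit_indices(10, 4, 2, 100, 10, c(0.3, 0.4))$SRMR,
               sqrt(mean(c(0.09, 0.16))))
})

test_that("pruning is a fixed point when all loadings are significant", {
  ex <- exact_structure(vdiag = 1e-4)
  spec <- cfa_spec(data.frame(region = paste0("r", 1:6),
                              factor = rep(c("F1", "F2"), each = 3)))
  fit <- fit_cfa(spec, ex$gs)
  pruned <- prune_loadings(fit, ex$gs)
  expect_equal(pruned$estimates, fit$estimates, tolerance = 1e-6)
  expect_length(pruned$prune_log, 0)
})

test_that("pruning removes a planted null cross-loading", {
  ## truth: r4 loads only on F2; spec adds a spurious r4-F1 cross-loading
  removed <- 0
  for (s in 1:10) {
    tp <- truth_params(p = 6, k = 2,
                       loadings = local({
                         L <- matrix(0, 6, 2)
                         L[1:3, 1] <- 0.7; L[4:6, 2] <- 0.65; L
                       }),
                       m = 10000, n = 20000, n_ld_blocks = 20,
                       seed = 300 + s)
    st <- simulate_sumstats(tp)
    gs <- smooth_structure(standardize_structure(
      build_covariance_structure(st$tables, st$ld, n_blocks = 150)))
    spec <- cfa_spec(data.frame(
      region = c(paste0("trait0", 1:6), "trait04"),
      factor = c(rep(c("F1", "F2"), each = 3), "F1")))
    fit <- fit_cfa(spec, gs)
    if (!fit$converged) next
    pruned <- tryCatch(prune_loadings(fit, gs), error = function(e) NULL)
    if (is.null(pruned)) next
    kept <- pruned$spec$loadings
    if (!any(kept$region == "trait04" & kept$factor == "F1") &&
        sum(kept$region == "trait04") == 1)
      removed <- removed + 1
  }
  expect_gte(removed, 8)
})

test_that("greedy pruning matches exhaustive best-AIC subset on a toy model", {
  ex <- exact_structure(lam = c(0.8, 0.7, 0.6, 0.75, 0.65, 0.6),
                        vdiag = 1e-4)
  base <- data.frame(region = c(paste0("r", 1:6), "r2"),
                     factor = c(rep(c("F1", "F2"), each = 3), "F2"))
  fit <- fit_cfa(cfa_spec(base), ex$gs)
  pruned <- prune_loadings(fit, ex$gs)
  ## oracle: enumerate all loading subsets, keep valid fully-significant
  ## converged fits, pick minimum AIC
  n <- nrow(base)
  best <- NULL; best_aic <- Inf
  for (mask in 0:(2^n - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sub <- base[keep, , drop = FALSE]
    counts <- table(sub$factor)
    sub <- sub[sub$factor %in% names(counts)[counts >= 2], , drop = FALSE]
    if (nrow(sub) < 4) next
    f <- tryCatch(fit_cfa(cfa_spec(sub), ex$gs), error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged)) next
    lam <- grep("^lambda", names(f$estimates))
    pv <- 2 * pnorm(-abs(f$estimates[lam] / f$se[lam]))
    if (any(is.na(pv)) || any(pv >= 0.05)) next
    ## coverage-corrected AIC so subsets spanning fewer regions compare
    ## like with like (as in select_model)
    aic <- gibnet:::embedded_aic(f, ex$gs)
    if (is.null(best) || aic < best_aic) { best <- f; best_aic <- aic }
  }
  expect_false(is.null(best))
  key <- function(f) paste(sort(paste(f$spec$loadings$region,
                                      f$spec$loadings$factor)),
                           collapse = ";")
  expect_equal(key(pruned), key(best))
})

test_that("model selection minimizes AIC with deterministic tie-breaks", {
  mk <- function(aic, npar, nf, conv = TRUE)
    structure(list(AIC = aic, npar = npar, n_factors = nf, converged = conv,
                   diagnostic = NULL, spec = list(regions = paste0("r", 1:4))),
              class = "cfa_fit")
  fits <- list(mk(30, 8, 2), mk(25, 8, 2), mk(40, 9, 3))
  expect_equal(select_model(fits)$AIC, 25)
  tie <- list(mk(25, 8, 2), mk(25, 6, 2))
  expect_equal(select_model(tie)$npar, 6)
  tie2 <- list(mk(25, 6, 3), mk(25, 6, 2))
  expect_equal(select_model(tie2)$n_factors, 2)
  expect_error(select_model(list(mk(25, 8, 2, conv = FALSE))),
               "no converged")
})

test_that("coverage-corrected selection rejects region-dropping shortcuts", {
  std <- shared_std("even")
  full <- fit_cfa(true_spec(), std)
  small_spec <- cfa_spec(data.frame(region = sprintf("trait%02d", 1:4),
                                    factor = "F1"))
  small <- fit_cfa(small_spec, std)
  ## the subset model has the smaller raw AIC purely by spanning fewer
  ## elements, but embedding in the common universe reverses the ranking
  expect_lt(small$AIC, full$AIC)
  sel <- select_model(list(small, full), std)
  expect_equal(sel$n_factors, 2)
})

test_that("SRMR is invariant under region reordering and CFI is capped", {
  ex <- exact_structure(vdiag = 1e-4)
  spec <- cfa_spec(data.frame(region = paste0("r", 1:6),
                              factor = rep(c("F1", "F2"), each = 3)))
  fit <- fit_cfa(spec, ex$gs)
  perm <- c(4, 5, 6, 1, 2, 3)
  gs2 <- gibnet:::subset_covstruct(ex$gs, ex$gs$traits[perm])
  fit2 <- fit_cfa(spec, gs2)
  expect_equal(fit$SRMR, fit2$SRMR, tolerance = 1e-6)
  expect_lte(fit$CFI, 1)
  expect_lte(fit2$CFI, 1)
})
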