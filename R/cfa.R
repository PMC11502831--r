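## Confirmatory factor analysis of a genetic covariance structure by
## diagonally weighted least squares (DWLS).
##
## The model-implied covariance is Sigma(theta) = Lambda Psi Lambda' + Theta
## with Lambda the pattern loading matrix (free entries given by the spec),
## Psi the factor correlation matrix (unit diagonal; off-diagonals free when
## the spec allows), and Theta diagonal residual variances. Factors are
## identified by unit variance. The discrepancy
##   F(theta) = (s - sigma(theta))' W^-1 (s - sigma(theta)),  W = diag(V)
## is minimized by quasi-Newton from three deterministic starts. Parameter
## standard errors use the sandwich
##   (D'W^-1 D)^-1 D'W^-1 V W^-1 D (D'W^-1 D)^-1,  D = d sigma / d theta,
## and the model chi-square is the residual quadratic form against the
## eigen-pseudoinverse of the full sampling covariance V, with
## df = q - (number of free parameters).

#' Construct a confirmatory factor model specification
#'
#' @param loadings data.frame with columns `region` and `factor` listing
#'   the freely estimated loadings.
#' @param psi_free are factor correlations free? (default TRUE)
#' @param start optional named numeric start values (names as in the fitted
#'   parameter vector, `lambda:<region>:<factor>` etc.).
#' @return object of class `cfa_spec`.
#' @export
cfa_spec <- function(loadings, psi_free = TRUE, start = NULL) {
  stopifnot(is.data.frame(loadings),
            all(c("region", "factor") %in% names(loadings)))
  loadings$region <- as.character(loadings$region)
  loadings$factor <- as.character(loadings$factor)
  factors <- unique(loadings$factor)
  counts <- table(loadings$factor)
  if (any(counts < 2))
    stop("every factor needs at least 2 free loadings; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  structure(list(regions = unique(loadings$region), factors = factors,
                 loadings = loadings[c("region", "factor")],
                 psi_free = psi_free, start = start),
            class = "cfa_spec")
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat(sprintf("<cfa_spec> %d regions, %d factor(s)\n",
              length(x$regions), length(x$factors)))
  for (f in x$factors)
    cat(sprintf("  %s: %s\n", f,
                paste(x$loadings$region[x$loadings$factor == f],
                      collapse = " ")))
  invisible(x)
}

#' Build a CFA specification from an EFA solution
#'
#' Carries forward the positive rotated loadings strictly greater than
#' `cutoff`; cross-loadings are retained whenever they exceed the cutoff.
#' Factors left with fewer than two supra-threshold indicators are removed
#' (single regions do not constitute factors), and regions with no
#' surviving loading are excluded from the specification. Factor
#' correlations are free. The EFA loadings are kept as optimizer start
#' values.
#'
#' @param efa an `efa_result`.
#' @param cutoff loading threshold (the study grid uses 0.3 and 0.5).
#' @return a `cfa_spec`.
#' @export
build_cfa_spec <- function(efa, cutoff) {
  if (!isTRUE(efa$converged)) stop("EFA did not converge; no spec built")
  L <- efa$loadings
  keep <- which(L > cutoff, arr.ind = TRUE)
  if (nrow(keep) == 0) stop("no viable spec at cutoff ", cutoff)
  df <- data.frame(region = rownames(L)[keep[, 1]],
                   factor = colnames(L)[keep[, 2]],
                   value = L[keep], stringsAsFactors = FALSE)
  counts <- table(df$factor)
  df <- df[df$factor %in% names(counts)[counts >= 2], , drop = FALSE]
  if (nrow(df) == 0) stop("no viable spec at cutoff ", cutoff)
  ## renumber surviving factors in their original order
  old <- intersect(colnames(L), unique(df$factor))
  relabel <- stats::setNames(paste0("F", seq_along(old)), old)
  df$factor <- unname(relabel[df$factor])
  start <- stats::setNames(df$value,
                           paste0("lambda:", df$region, ":", df$factor))
  cfa_spec(df[c("region", "factor")], psi_free = TRUE, start = start)
}

## ---- internal parameterization -------------------------------------------

## index bookkeeping for the free parameter vector
## order: lambda (as listed in spec), psi lower-triangle (col-major), theta
par_layout <- function(spec) {
  p <- length(spec$regions); k <- length(spec$factors)
  m <- nrow(spec$loadings)
  lam_idx <- cbind(match(spec$loadings$region, spec$regions),
                   match(spec$loadings$factor, spec$factors))
  npsi <- if (spec$psi_free && k >= 2) k * (k - 1) / 2 else 0
  psi_idx <- if (npsi > 0) {
    ix <- vech_index(k)
    ix[ix[, 1] != ix[, 2], , drop = FALSE]
  } else matrix(integer(0), 0, 2)
  names <- c(paste0("lambda:", spec$loadings$region, ":",
                    spec$loadings$factor),
             if (npsi > 0) paste0("psi:", spec$factors[psi_idx[, 2]], ":",
                                  spec$factors[psi_idx[, 1]]),
             paste0("theta:", spec$regions))
  list(p = p, k = k, m = m, npsi = npsi, lam_idx = lam_idx,
       psi_idx = psi_idx, npar = m + npsi + p, names = names)
}

par_unpack <- function(par, lay, spec) {
  Lam <- matrix(0, lay$p, lay$k,
                dimnames = list(spec$regions, spec$factors))
  Lam[lay$lam_idx] <- par[seq_len(lay$m)]
  Psi <- diag(lay$k)
  if (lay$npsi > 0) {
    v <- par[lay$m + seq_len(lay$npsi)]
    Psi[lay$psi_idx] <- v
    Psi[lay$psi_idx[, c(2, 1), drop = FALSE]] <- v
  }
  Th <- par[lay$m + lay$npsi + seq_len(lay$p)]
  list(Lam = Lam, Psi = Psi, Th = Th)
}

implied_vech <- function(par, lay, spec) {
  u <- par_unpack(par, lay, spec)
  vech(u$Lam %*% u$Psi %*% t(u$Lam) + diag(u$Th, lay$p))
}

## q x npar Jacobian d vech(Sigma) / d theta
delta_matrix <- function(par, lay, spec) {
  u <- par_unpack(par, lay, spec)
  p <- lay$p
  q <- p * (p + 1) / 2
  D <- matrix(0, q, lay$npar)
  LP <- u$Lam %*% u$Psi                      # p x k
  low <- lower.tri(diag(p), diag = TRUE)
  col <- 0
  for (a in seq_len(lay$m)) {
    r <- lay$lam_idx[a, 1]; f <- lay$lam_idx[a, 2]
    v <- LP[, f]
    dS <- matrix(0, p, p)
    dS[r, ] <- dS[r, ] + v
    dS[, r] <- dS[, r] + v
    D[, col + a] <- dS[low]
  }
  col <- lay$m
  for (a in seq_len(lay$npsi)) {
    f <- lay$psi_idx[a, 1]; g <- lay$psi_idx[a, 2]
    dS <- tcrossprod(u$Lam[, f], u$Lam[, g])
    dS <- dS + t(dS)
    D[, col + a] <- dS[low]
  }
  col <- lay$m + lay$npsi
  diag_pos <- which(vech_index(p)[, 1] == vech_index(p)[, 2])
  for (r in seq_len(p)) D[diag_pos[r], col + r] <- 1
  D
}

## closed-form DWLS fit of the independence model (Sigma = diag residuals)
independence_fit <- function(gs) {
  p <- length(gs$traits)
  s <- vech(gs$S)
  sigma <- vech(diag(diag(gs$S), p))
  r <- s - sigma
  Vp <- pseudoinverse(gs$V)
  chi2 <- drop(t(r) %*% Vp %*% r)
  list(chi2 = chi2, df = p * (p + 1) / 2 - p, npar = p)
}

#' Model fit indices
#'
#' AIC, CFI and SRMR from a fitted model and the independence baseline on
#' the same structure: `AIC = chi2 + 2 npar`;
#' `CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)`
#' (1 by convention when the denominator is zero); SRMR is the root mean
#' square of the `q` unique standardized residuals.
#'
#' @param chi2,df,npar model statistic, degrees of freedom, free-parameter
#'   count.
#' @param chi2_b,df_b baseline (independence-model) statistic and df.
#' @param resid_std vech of the standardized residual matrix.
#' @return list with `AIC`, `CFI`, `SRMR`.
#' @export
fit_indices <- function(chi2, df, npar, chi2_b, df_b, resid_std) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  list(AIC = chi2 + 2 * npar,
       CFI = if (den <= 0) 1 else 1 - num / den,
       SRMR = sqrt(mean(resid_std^2)))
}

#' Fit a confirmatory factor model by diagonally weighted least squares
#'
#' Fits the specified loading pattern to a standardized, PSD-smoothed
#' genetic covariance structure. See the package vignette for the
#' estimator, the sandwich covariance, and the chi-square construction.
#' Residual variances are bounded below at 1e-6; a solution at the bound
#' (Heywood case) or an optimizer failure is returned with
#' `converged = FALSE` and undefined fit indices.
#'
#' @param spec a `cfa_spec`; its regions must be a subset of the structure's
#'   traits.
#' @param gs a standardized `covstruct` whose S has been smoothed to PSD.
#' @param start optional numeric vector of start values (full parameter
#'   vector, in `par_names` order).
#' @return object of class `cfa_fit`.
#' @export
fit_cfa <- function(spec, gs, start = NULL) {
  if (!all(spec$regions %in% gs$traits))
    stop("spec regions missing from structure: ",
         paste(setdiff(spec$regions, gs$traits), collapse = ", "))
  gs <- subset_covstruct(gs, spec$regions)
  lay <- par_layout(spec)
  s <- vech(gs$S)
  q <- length(s)
  w <- diag(gs$V)
  if (all(w <= 0)) stop("sampling covariance V has no positive diagonal")
  ## zero-variance elements (the unit diagonal of a standardized S) get the
  ## smallest positive weight denominator: they are fitted exactly anyway
  w[w <= 0] <- min(w[w > 0])

  obj <- function(par) {
    r <- s - implied_vech(par, lay, spec)
    sum(r^2 / w)
  }
  grad <- function(par) {
    r <- s - implied_vech(par, lay, spec)
    D <- delta_matrix(par, lay, spec)
    drop(-2 * crossprod(D, r / w))
  }

  lower <- c(rep(-10, lay$m), rep(-0.995, lay$npsi), rep(1e-6, lay$p))
  upper <- c(rep(10, lay$m), rep(0.995, lay$npsi), rep(100, lay$p))

  diag_s <- diag(gs$S)[match(spec$regions, gs$traits)]
  starts <- list()
  if (!is.null(start)) starts <- c(starts, list(start))
  if (!is.null(spec$start)) {
    p0 <- c(rep(0.5, lay$m), rep(0.3, lay$npsi), rep(0.5, lay$p))
    names(p0) <- lay$names
    hit <- intersect(names(spec$start), lay$names)
    p0[hit] <- pmin(pmax(spec$start[hit], lower[match(hit, lay$names)]),
                    upper[match(hit, lay$names)])
    starts <- c(starts, list(unname(p0)))
  }
  starts <- c(starts,
              list(c(rep(0.5, lay$m), rep(0.3, lay$npsi),
                     pmax(diag_s * 0.5, 0.1)),
                   c(0.5 + 0.1 * (-1)^seq_len(lay$m), rep(0, lay$npsi),
                     pmax(diag_s * 0.3, 0.05))))

  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(
      stats::optim(p0, obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }

  if (is.null(best)) {
    return(structure(list(spec = spec, converged = FALSE,
                          diagnostic = "optimizer failed from all starts",
                          estimates = NULL, se = NULL, chi2 = NA_real_,
                          df = NA_integer_, npar = lay$npar, AIC = NA_real_,
                          CFI = NA_real_, SRMR = NA_real_,
                          n_factors = length(spec$factors),
                          par_names = lay$names),
                     class = "cfa_fit"))
  }

  par <- best$par
  th <- par[lay$m + lay$npsi + seq_len(lay$p)]
  psi <- if (lay$npsi > 0) par[lay$m + seq_len(lay$npsi)] else numeric(0)
  heywood <- any(th <= 1e-6 + 1e-9)
  psi_bound <- lay$npsi > 0 && any(abs(psi) >= 0.995 - 1e-9)
  converged <- best$convergence == 0 && !heywood && !psi_bound
  diagnostic <- c(if (best$convergence != 0) best$message,
                  if (heywood) "Heywood case: residual variance at bound",
                  if (psi_bound) "factor correlation at bound")

  sigma <- implied_vech(par, lay, spec)
  r <- s - sigma
  D <- delta_matrix(par, lay, spec)

  ## sandwich parameter covariance
  se <- rep(NA_real_, lay$npar)
  bread_ok <- tryCatch({
    B <- crossprod(D, D / w)
    bread <- solve(B)
    meat <- crossprod(D / w, gs$V %*% (D / w))
    cv <- bread %*% meat %*% bread
    se <- sqrt(pmax(diag(cv), 0))
    TRUE
  }, error = function(e) FALSE)
  if (!bread_ok)
    diagnostic <- c(diagnostic, "singular information; no standard errors")

  Vp <- pseudoinverse(gs$V)
  chi2 <- drop(t(r) %*% Vp %*% r)
  df <- q - lay$npar
  base <- independence_fit(gs)
  Sig <- unvech(sigma, lay$p)
  resid_std <- vech(stats::cov2cor(gs$S) -
                      stats::cov2cor(Sig + diag(1e-12, lay$p)))
  fi <- fit_indices(chi2, df, lay$npar, base$chi2, base$df, resid_std)

  structure(list(spec = spec, converged = converged,
                 diagnostic = if (length(diagnostic)) diagnostic else NULL,
                 estimates = stats::setNames(par, lay$names),
                 se = stats::setNames(se, lay$names),
                 chi2 = chi2, df = df, npar = lay$npar,
                 chi2_baseline = base$chi2, df_baseline = base$df,
                 AIC = if (converged) fi$AIC else NA_real_,
                 CFI = if (converged) fi$CFI else NA_real_,
                 SRMR = if (converged) fi$SRMR else NA_real_,
                 n_factors = length(spec$factors),
                 objective = best$value, par_names = lay$names,
                 loadings_matrix = par_unpack(par, lay, spec)$Lam,
                 psi_matrix = par_unpack(par, lay, spec)$Psi,
                 theta_resid = par_unpack(par, lay, spec)$Th),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> %d factor(s), %d free parameters, converged = %s\n",
              x$n_factors, x$npar, x$converged))
  if (x$converged)
    cat(sprintf("  chi2 = %.2f (df %d), AIC = %.2f, CFI = %.3f, SRMR = %.4f\n",
                x$chi2, x$df, x$AIC, x$CFI, x$SRMR))
  if (!is.null(x$diagnostic)) cat("  ", paste(x$diagnostic, collapse = "; "), "\n")
  invisible(x)
}

#' Prune non-significant factor loadings
#'
#' Iteratively removes the free loading with the largest two-sided Wald
#' p-value at or above `alpha`, refits, and repeats until all remaining
#' loadings are significant. A factor reduced below two indicators is
#' removed entirely (with its correlations); regions left without loadings
#' drop out of the specification.
#'
#' @param fit a converged `cfa_fit`.
#' @param gs the standardized `covstruct` the fit was estimated on.
#' @param alpha significance level (default 0.05).
#' @return the final refitted `cfa_fit`, with a `prune_log` character
#'   vector of removals.
#' @export
prune_loadings <- function(fit, gs, alpha = 0.05) {
  if (!isTRUE(fit$converged)) stop("cannot prune a non-converged fit")
  log <- character(0)
  repeat {
    est <- fit$estimates; se <- fit$se
    lam <- grep("^lambda:", names(est))
    pv <- 2 * stats::pnorm(-abs(est[lam] / se[lam]))
    worst <- which.max(pv)
    if (length(pv) == 0 || is.na(pv[worst]) || pv[worst] < alpha) break
    drop_name <- names(est)[lam[worst]]
    parts <- strsplit(drop_name, ":")[[1]]
    log <- c(log, sprintf("removed %s (p = %.3g)", drop_name, pv[worst]))
    ld <- fit$spec$loadings
    ld <- ld[!(ld$region == parts[2] & ld$factor == parts[3]), , drop = FALSE]
    counts <- table(ld$factor)
    gone <- names(counts)[counts < 2]
    if (length(gone) > 0) {
      log <- c(log, sprintf("removed factor %s (single indicator left)",
                            paste(gone, collapse = ", ")))
      ld <- ld[!(ld$factor %in% gone), , drop = FALSE]
    }
    if (nrow(ld) == 0)
      stop("pruning emptied the model; log: ", paste(log, collapse = "; "))
    spec2 <- cfa_spec(ld, psi_free = fit$spec$psi_free,
                      start = stats::setNames(fit$estimates,
                                              names(fit$estimates)))
    ## reuse surviving estimates as start values
    spec2$start <- fit$estimates[intersect(names(fit$estimates),
                                           par_layout(spec2)$names)]
    fit <- fit_cfa(spec2, gs)
    if (!isTRUE(fit$converged))
      stop("refit after pruning did not converge; log: ",
           paste(log, collapse = "; "))
  }
  fit$prune_log <- log
  fit
}

## AIC of a fitted model embedded in the full trait universe: regions the
## spec excludes are modeled as residual-only variables (zero loadings,
## residual variance fitted exactly), so models covering different region
## subsets become comparable — a model that drops regions must defend the
## implied claim that they are genetically uncorrelated with the rest.
embedded_aic <- function(fit, gs) {
  traits <- gs$traits
  sel <- match(fit$spec$regions, traits)
  p <- length(traits)
  Sig <- diag(diag(gs$S), p)
  u <- fit$loadings_matrix %*% fit$psi_matrix %*% t(fit$loadings_matrix) +
    diag(fit$theta_resid, length(sel))
  Sig[sel, sel] <- u
  r <- vech(gs$S) - vech(Sig)
  chi2 <- drop(t(r) %*% pseudoinverse(gs$V) %*% r)
  chi2 + 2 * (fit$npar + (p - length(sel)))
}

#' Select the best-fitting model
#'
#' Returns the converged fit with minimal AIC; ties are broken by fewer
#' free parameters, then fewer factors. When the common covariance
#' structure `gs` is supplied and the candidates cover different region
#' subsets, each candidate is first embedded in the full trait universe
#' (excluded regions as residual-only variables) so that the AICs compare
#' like with like; candidates with identical coverage are unaffected.
#'
#' @param fits list of `cfa_fit` objects.
#' @param gs optional `covstruct` the fits were estimated on, enabling the
#'   coverage-corrected comparison.
#' @return the selected `cfa_fit`.
#' @export
select_model <- function(fits, gs = NULL) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) {
    diags <- vapply(fits, function(f)
      paste0(f$n_factors, "-factor: ",
             paste(f$diagnostic %||% "not converged", collapse = "; ")),
      character(1))
    stop("no converged fits to select from:\n  ",
         paste(diags, collapse = "\n  "))
  }
  aic <- vapply(conv, `[[`, numeric(1), "AIC")
  if (!is.null(gs)) {
    cover <- lapply(conv, function(f) sort(f$spec$regions))
    if (length(unique(cover)) > 1)
      aic <- vapply(conv, embedded_aic, numeric(1), gs = gs)
  }
  npar <- vapply(conv, `[[`, numeric(1), "npar")
  nf <- vapply(conv, `[[`, numeric(1), "n_factors")
  conv[[order(aic, npar, nf)[1]]]
}
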