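## Spatial overlap of factor-defined region sets with reference
## parcellations: weighted Dice coefficient, permutation null preserving
## the set size, and Benjamini-Hochberg FDR over each comparison grid.

#' Construct a region set
#'
#' A named subset of a declared region universe, with optional
#' non-negative per-region weights (e.g. region volumes) under which the
#' Dice coefficient becomes a percent-volume overlap.
#'
#' @param name set label.
#' @param members character vector, a subset of `universe`.
#' @param universe character vector of all region names.
#' @param weights optional named non-negative weights covering the
#'   universe (unit weights when omitted).
#' @return object of class `region_set`.
#' @export
region_set <- function(name, members, universe, weights = NULL) {
  members <- unique(as.character(members))
  if (!all(members %in% universe))
    stop("members outside the region universe: ",
         paste(setdiff(members, universe), collapse = ", "))
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(universe)), universe)
  } else {
    stopifnot(all(universe %in% names(weights)), all(weights >= 0))
    weights <- weights[universe]
  }
  structure(list(name = name, members = members, universe = universe,
                 weights = weights),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s: {%s} of %d-region universe\n",
              x$name, paste(x$members, collapse = ", "),
              length(x$universe)))
  invisible(x)
}

#' Dice coefficient between two region sets
#'
#' `DC = 2 w(a intersect b) / (w(a) + w(b))` with `w` the sum of region
#' weights (unit weights reproduce the set-count Dice). Both sets empty
#' is undefined and returns `NA` with a warning.
#'
#' @param a,b `region_set`s over the same universe.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(sort(a$universe), sort(b$universe)))
    stop("region sets live on different universes")
  w <- a$weights
  wa <- sum(w[a$members]); wb <- sum(w[b$members])
  if (wa + wb == 0) {
    warning("both region sets empty; Dice undefined")
    return(NA_real_)
  }
  2 * sum(w[intersect(a$members, b$members)]) / (wa + wb)
}

#' Permutation p-value for a Dice overlap
#'
#' Draws `n_iter` random region sets of size `a_size` uniformly without
#' replacement from the universe, computes each draw's Dice coefficient
#' against the fixed reference set `b`, and returns the add-one estimator
#' `p = (1 + #\{DC_perm >= observed\}) / (1 + n_iter)`; the smallest
#' attainable value is `1 / (n_iter + 1)`. Reproducible given `seed`.
#'
#' @param a_size size of the permuted set (the factor's region count).
#' @param b reference `region_set` (weights stay fixed).
#' @param universe region universe to draw from.
#' @param observed the observed Dice coefficient.
#' @param n_iter permutation iterations (default 1000).
#' @param seed RNG seed.
#' @param weights optional named weights over the universe.
#' @return permutation p-value.
#' @export
permutation_pvalue <- function(a_size, b, universe, observed,
                               n_iter = 1000, seed = 1, weights = NULL) {
  if (a_size > length(universe))
    stop("a_size exceeds the universe size")
  stopifnot(n_iter >= 1)
  w <- if (is.null(weights))
    stats::setNames(rep(1, length(universe)), universe) else weights[universe]
  wb <- sum(w[b$members])
  perm <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    draw <- sample(universe, a_size)
    2 * sum(w[intersect(draw, b$members)]) / (sum(w[draw]) + wb)
  }, numeric(1)))
  (1 + sum(perm >= observed)) / (1 + n_iter)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotonicity-enforced and capped at 1; the
#' output order matches the input.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  ## p-values of exactly 0 (numerical underflow of extreme Z) are accepted
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Overlap grid with one FDR family
#'
#' All pairwise Dice coefficients between factor region sets and reference
#' sets, a permutation p-value per pair (per-pair seeds derived from
#' `seed`), and BH-FDR applied across the full grid as one family.
#'
#' @param gibns list of factor `region_set`s.
#' @param references list of reference `region_set`s.
#' @param n_iter permutation iterations per pair (default 1000).
#' @param seed root RNG seed.
#' @return data.frame with columns `gibn, reference, dice, p_perm, p_fdr,
#'   n_iter, seed`.
#' @export
overlap_grid <- function(gibns, references, n_iter = 1000, seed = 1) {
  if (length(gibns) == 0 || length(references) == 0)
    stop("empty region-set lists")
  rows <- list()
  i <- 0
  for (g in gibns) for (r in references) {
    i <- i + 1
    dc <- dice(g, r)
    pp <- permutation_pvalue(length(g$members), r, g$universe, dc,
                             n_iter = n_iter, seed = seed + i,
                             weights = g$weights)
    rows[[i]] <- data.frame(gibn = g$name, reference = r$name, dice = dc,
                            p_perm = pp, n_iter = n_iter, seed = seed + i,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_perm)
  out[c("gibn", "reference", "dice", "p_perm", "p_fdr", "n_iter", "seed")]
}

#' Genetic correlation of factors with external traits
#'
#' Cross-trait LDSC of each factor's multivariate GWAS against each
#' external phenotype, with BH-FDR across the full factor-by-trait family.
#' Factor orientation follows the EFA sign convention (per-factor loading
#' sums positive).
#'
#' @param factor_tables named list of factor `sumstats` (see
#'   [factor_gwas_to_sumstats()]); each must carry effective N.
#' @param external_tables named list of munged external-trait `sumstats`.
#' @param ld an `ldscores` data.frame.
#' @param n_blocks jackknife blocks for the LDSC fits.
#' @return data.frame with columns `factor, trait, rg, se, p, p_fdr`.
#' @export
factor_trait_rg <- function(factor_tables, external_tables, ld,
                            n_blocks = 200) {
  rows <- list()
  for (f in names(factor_tables)) for (t in names(external_tables)) {
    ct <- bivariate_ldsc(factor_tables[[f]], external_tables[[t]], ld,
                         n_blocks = n_blocks)
    rows[[length(rows) + 1]] <-
      data.frame(factor = f, trait = t, rg = ct$rg, se = ct$se_rg,
                 p = ct$p_rg, gcov = ct$gcov, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- bh_fdr(out$p[ok])
  out[c("factor", "trait", "rg", "se", "p", "p_fdr", "gcov")]
}
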