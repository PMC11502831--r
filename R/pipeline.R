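## End-to-end orchestration: munge -> parity split -> (S, V) per parity ->
## EFA grid -> thresholded CFA specs -> DWLS fits -> pruning -> AIC
## selection -> factor GWAS -> clumping -> external genetic correlations ->
## parcellation overlap. Every stage logs input/output row counts.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Inputs
#' are either file-based (`trait_files` + `ld_files`) or generated in
#' memory by the synthetic module (`simulate = list(...)` of
#' [truth_params()] arguments). Defaults mirror the study settings: EFA on
#' odd chromosomes and CFA on even, 1-10 factors, loading cutoffs 0.3 and
#' 0.5, pruning alpha 0.05, genome-wide significance 5e-8, 250 kb clump
#' window, 1000 permutation iterations.
#'
#' @param trait_files named character vector of summary-statistics paths.
#' @param column_map column mapping passed to [read_sumstats()].
#' @param ld_files,ld_m_files LD-score and M file paths.
#' @param reference_file optional allele/frequency reference for [munge()].
#' @param simulate optional list of [truth_params()] arguments; replaces
#'   the file inputs.
#' @param parity_efa,parity_cfa chromosome parities for the two stages;
#'   must be complementary.
#' @param factor_range candidate factor counts (clipped to p - 1).
#' @param cutoffs loading thresholds carried from EFA to CFA.
#' @param prune_alpha loading-pruning significance level.
#' @param gws_threshold genome-wide significance threshold.
#' @param clump_window clump half-window (bp).
#' @param n_blocks LDSC jackknife blocks.
#' @param n_iter permutation iterations for the overlap stage.
#' @param seed root seed for all randomness.
#' @param external_files named external-trait summary statistics for the
#'   genetic-correlation stage (optional).
#' @param region_sets optional list with `gibns` and `references` (lists of
#'   [region_set()]s) for the overlap stage.
#' @param out_dir output directory for artifacts (optional).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(trait_files = NULL, column_map = NULL,
                            ld_files = NULL, ld_m_files = NULL,
                            reference_file = NULL, simulate = NULL,
                            parity_efa = "odd", parity_cfa = "even",
                            factor_range = 1:10, cutoffs = c(0.3, 0.5),
                            prune_alpha = 0.05, gws_threshold = 5e-8,
                            clump_window = 250000, n_blocks = 200,
                            n_iter = 1000, seed = 1,
                            external_files = NULL, region_sets = NULL,
                            out_dir = NULL) {
  if (!parity_efa %in% c("odd", "even") || !parity_cfa %in% c("odd", "even"))
    stop("parities must be 'odd' or 'even'")
  if (parity_efa == parity_cfa)
    stop("EFA and CFA parities must be complementary, both are '",
         parity_efa, "'")
  if (is.null(simulate) && is.null(trait_files))
    stop("either trait_files or a simulate block is required")
  stopifnot(all(factor_range >= 1), length(cutoffs) >= 1)
  structure(list(trait_files = trait_files, column_map = column_map,
                 ld_files = ld_files, ld_m_files = ld_m_files,
                 reference_file = reference_file, simulate = simulate,
                 parity_efa = parity_efa, parity_cfa = parity_cfa,
                 factor_range = factor_range, cutoffs = cutoffs,
                 prune_alpha = prune_alpha, gws_threshold = gws_threshold,
                 clump_window = clump_window, n_blocks = n_blocks,
                 n_iter = n_iter, seed = seed,
                 external_files = external_files, region_sets = region_sets,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$trait_files)) raw$trait_files <- unlist(raw$trait_files)
  if (!is.null(raw$factor_range) && length(raw$factor_range) == 2)
    raw$factor_range <- raw$factor_range[1]:raw$factor_range[2]
  do.call(pipeline_config, raw)
}

stage_log <- function(log, stage, n_in, n_out, note = "") {
  entry <- sprintf("%s\tstage=%s\tn_in=%d\tn_out=%d\t%s",
                   format(Sys.time(), "%Y-%m-%d %H:%M:%OS2"),
                   stage, n_in, n_out, note)
  c(log, entry)
}

#' Run the full analysis pipeline
#'
#' Executes every stage from summary statistics to selected factor model,
#' factor GWAS, loci, external genetic correlations, and parcellation
#' overlap, per the configuration. Deterministic given the configured
#' seed.
#'
#' @param config a `pipeline_config`.
#' @param sensitivity swap the EFA/CFA parities and rerun (the
#'   chromosome-order sensitivity analysis).
#' @param gwas run the factor-GWAS, clumping and external-correlation
#'   stages (default TRUE); FALSE stops after model selection.
#' @return object of class `run_artifacts`: list with the per-parity
#'   structures, EFA and CFA tables, selected model, GWAS, loci, rg and
#'   overlap tables, and the stage log.
#' @export
run_pipeline <- function(config, sensitivity = FALSE, gwas = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (sensitivity) {
    tmp <- config$parity_efa
    config$parity_efa <- config$parity_cfa
    config$parity_cfa <- tmp
  }
  log <- character(0)

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% config$seed
    study <- simulate_sumstats(do.call(truth_params, args))
    tables <- study$tables
    ld <- study$ld
    log <- stage_log(log, "simulate", 0, nrow(ld),
                     sprintf("p=%d seed=%d", length(tables), args$seed))
  } else {
    tables <- lapply(names(config$trait_files), function(nm)
      read_sumstats(config$trait_files[[nm]], config$column_map,
                    trait_name = nm))
    names(tables) <- names(config$trait_files)
    ld <- read_ldscores(config$ld_files, config$ld_m_files)
    log <- stage_log(log, "read", length(tables), nrow(ld), "")
    if (!is.null(config$reference_file)) {
      ref <- read_sumstats(config$reference_file)
      n0 <- sum(vapply(tables, nrow, integer(1)))
      tables <- lapply(tables, munge, ref = ref)
      log <- stage_log(log, "munge", n0,
                       sum(vapply(tables, nrow, integer(1))), "")
    }
  }
  p <- length(tables)

  ## ---- parity split and covariance structures ----
  structures <- list()
  for (parity in c(config$parity_efa, config$parity_cfa)) {
    split <- lapply(tables, select_chromosome_parity, parity = parity)
    gs <- build_covariance_structure(split, ld, n_blocks = config$n_blocks)
    std <- smooth_structure(standardize_structure(gs))
    structures[[parity]] <- list(raw = gs, std = std)
    log <- stage_log(log, paste0("ldsc_", parity), nrow(tables[[1]]),
                     nrow(split[[1]]),
                     sprintf("k=%d q=%d", p, p * (p + 1) / 2))
  }
  gs_efa <- structures[[config$parity_efa]]$std
  gs_cfa <- structures[[config$parity_cfa]]$std

  ## ---- EFA grid ----
  factor_range <- config$factor_range[config$factor_range <= p - 1]
  efas <- lapply(factor_range, function(k)
    tryCatch(run_efa(gs_efa, k), error = function(e) NULL))
  names(efas) <- paste0("k", factor_range)
  efa_table <- do.call(rbind, lapply(seq_along(efas), function(i) {
    e <- efas[[i]]
    data.frame(n_factors = factor_range[i],
               converged = !is.null(e) && isTRUE(e$converged),
               stringsAsFactors = FALSE)
  }))
  log <- stage_log(log, "efa", length(factor_range), sum(efa_table$converged),
                   sprintf("k in [%d, %d]", min(factor_range),
                           max(factor_range)))

  ## ---- CFA specs at each cutoff, fitted on the other parity ----
  fits <- list()
  cfa_rows <- list()
  for (i in seq_along(efas)) {
    e <- efas[[i]]
    if (is.null(e) || !isTRUE(e$converged)) next
    for (cutoff in config$cutoffs) {
      spec <- tryCatch(build_cfa_spec(e, cutoff), error = function(err) NULL)
      if (is.null(spec)) next
      fit <- fit_cfa(spec, gs_cfa)
      if (isTRUE(fit$converged))
        fit <- tryCatch(prune_loadings(fit, gs_cfa, config$prune_alpha),
                        error = function(err) fit)
      key <- sprintf("k%d_cut%.1f", factor_range[i], cutoff)
      fits[[key]] <- fit
      cfa_rows[[key]] <- data.frame(
        efa_factors = factor_range[i], cutoff = cutoff,
        model_factors = fit$n_factors, npar = fit$npar,
        converged = fit$converged, chi2 = fit$chi2, df = fit$df,
        AIC = fit$AIC, CFI = fit$CFI, SRMR = fit$SRMR,
        stringsAsFactors = FALSE)
    }
  }
  if (length(fits) == 0) stop("stage cfa: no viable specifications")
  cfa_table <- do.call(rbind, cfa_rows)
  rownames(cfa_table) <- NULL
  log <- stage_log(log, "cfa", length(fits),
                   sum(cfa_table$converged), "pruned; both cutoffs")

  selected <- select_model(fits, gs_cfa)
  log <- stage_log(log, "select", length(fits), 1,
                   sprintf("%d factors, AIC=%.2f", selected$n_factors,
                           selected$AIC))

  ## ---- factor GWAS on the full data ----
  gwas_table <- NULL
  loci <- NULL
  rg_table <- NULL
  if (gwas) {
  gwas_table <- multivariate_gwas(tables, structures[[config$parity_cfa]]$raw,
                            selected$spec, selected)
  loci <- clump_loci(gwas_table, p_threshold = config$gws_threshold,
                     window = config$clump_window)
  log <- stage_log(log, "gwas", nrow(tables[[1]]), nrow(gwas_table),
                   paste0("lambda=", paste(round(attr(gwas_table, "lambda"), 3),
                                           collapse = ",")))
  log <- stage_log(log, "clump", nrow(gwas_table), nrow(loci), "")

  ## ---- external genetic correlations ----
  if (!is.null(config$external_files)) {
    ext <- lapply(names(config$external_files), function(nm)
      read_sumstats(config$external_files[[nm]], config$column_map,
                    trait_name = nm))
    names(ext) <- names(config$external_files)
    ftabs <- lapply(selected$spec$factors, function(f)
      factor_gwas_to_sumstats(gwas_table, f))
    names(ftabs) <- selected$spec$factors
    rg_table <- factor_trait_rg(ftabs, ext, ld, n_blocks = config$n_blocks)
    log <- stage_log(log, "rg", length(ftabs) * length(ext), nrow(rg_table),
                     "one FDR family")
  }
  }

  ## ---- parcellation overlap ----
  overlap_table <- NULL
  if (!is.null(config$region_sets)) {
    overlap_table <- overlap_grid(config$region_sets$gibns,
                                  config$region_sets$references,
                                  n_iter = config$n_iter,
                                  seed = config$seed)
    log <- stage_log(log, "overlap", length(config$region_sets$gibns) *
                       length(config$region_sets$references),
                     nrow(overlap_table), "one FDR family")
  }

  artifacts <- structure(
    list(config = config, structures = structures, efas = efas,
         efa_table = efa_table, cfa_table = cfa_table, fits = fits,
         selected = selected, gwas = gwas_table, loci = loci,
         rg_table = rg_table, overlap_table = overlap_table, log = log),
    class = "run_artifacts")
  if (!is.null(config$out_dir)) write_artifacts(artifacts, config$out_dir)
  artifacts
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat(sprintf("<run_artifacts> selected %d-factor model (AIC %.2f, CFI %.3f, SRMR %.4f)\n",
              x$selected$n_factors, x$selected$AIC, x$selected$CFI,
              x$selected$SRMR))
  invisible(x)
}

## serialize the tabular artifacts as TSV plus a human-readable model spec
write_artifacts <- function(artifacts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(as.data.frame(df), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(artifacts$efa_table, "efa_grid.tsv")
  wt(artifacts$cfa_table, "cfa_fits.tsv")
  wt(artifacts$gwas, "factor_gwas.tsv")
  wt(artifacts$loci, "loci.tsv")
  wt(artifacts$rg_table, "factor_trait_rg.tsv")
  wt(artifacts$overlap_table, "overlap.tsv")
  sel <- artifacts$selected
  lines <- c(sprintf("# selected model: %d factor(s), AIC=%.4f CFI=%.4f SRMR=%.5f",
                     sel$n_factors, sel$AIC, sel$CFI, sel$SRMR))
  for (f in sel$spec$factors) {
    rows <- sel$spec$loadings$factor == f
    regs <- sel$spec$loadings$region[rows]
    vals <- sel$estimates[paste0("lambda:", regs, ":", f)]
    lines <- c(lines, sprintf("%s: %s", f,
                              paste(sprintf("%s (%.3f)", regs, vals),
                                    collapse = " ")))
  }
  writeLines(lines, file.path(out_dir, "selected_model.txt"))
  writeLines(artifacts$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
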