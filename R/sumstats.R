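## GWAS summary-statistics I/O and harmonization.
##
## A `sumstats` object is a data.frame with one row per SNP and columns
##   snp, chr, bp, a1, a2, maf, beta, se, z, p, n, info
## plus attributes `trait_name` and `provenance` (a character log of the
## filters applied). Positions are 1-based; chromosomes are restricted to
## the autosomes 1-22.

SUMSTATS_COLS <- c("snp", "chr", "bp", "a1", "a2", "maf",
                   "beta", "se", "z", "p", "n", "info")

new_sumstats <- function(df, trait_name = "trait", provenance = character()) {
  for (col in SUMSTATS_COLS) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[SUMSTATS_COLS]
  df$snp <- as.character(df$snp)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  for (col in c("chr", "bp", "maf", "beta", "se", "z", "p", "n", "info"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df <- df[order(df$chr, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            trait_name = trait_name, provenance = provenance)
}

add_provenance <- function(tab, msg) {
  attr(tab, "provenance") <- c(attr(tab, "provenance"), msg)
  tab
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s': %d SNPs on %d chromosome(s)\n",
              attr(x, "trait_name"), nrow(x), length(unique(x$chr))))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  for (msg in attr(x, "provenance")) cat(" -", msg, "\n")
  invisible(x)
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited summary-statistics file into a
#' harmonized `sumstats` table. Column names are mapped through
#' `column_map`, a named character vector from canonical names
#' (`snp, chr, bp, a1, a2, maf, beta, se, z, p, n, info`) to the names used
#' in the file. Z-scores are computed as `beta/se` when no Z column is
#' mapped. Rows whose mandatory fields fail to parse are dropped and
#' counted in the provenance log. Missing values may be coded `NA`, `.` or
#' an empty field.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical column names
#'   to file column names. Defaults to the identity map on the canonical
#'   header written by [write_sumstats()].
#' @param trait_name label for the trait; defaults to the file name.
#' @param n_default constant sample size used when the file has no N
#'   column.
#' @return a `sumstats` data.frame.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NULL,
                          n_default = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ".", ""), check.names = FALSE)
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path)
  default_map <- c(snp = "SNP", chr = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
                   maf = "MAF", beta = "BETA", se = "SE", z = "Z", p = "P",
                   n = "N", info = "INFO")
  map <- default_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  map <- map[map %in% names(raw)]

  required <- c("snp", "a1", "a2")
  missing_req <- setdiff(required, names(map))
  if (length(missing_req) > 0)
    stop("required column(s) missing from file: ",
         paste(missing_req, collapse = ", "))
  if (!("z" %in% names(map)) && !all(c("beta", "se") %in% names(map)))
    stop("required column(s) missing from file: z (or beta and se)")
  if (!("n" %in% names(map)) && is.null(n_default))
    stop("required column(s) missing from file: n ",
         "(supply n_default for files without a sample-size column)")

  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in names(map)) df[[nm]] <- raw[[map[[nm]]]]
  if (is.null(df$n)) df$n <- n_default

  tab <- new_sumstats(df, trait_name = trait_name %||% basename(path))
  ## back-fill z from beta/se, beta/se from z where a scale is available
  miss_z <- is.na(tab$z) & !is.na(tab$beta) & !is.na(tab$se)
  tab$z[miss_z] <- tab$beta[miss_z] / tab$se[miss_z]
  miss_p <- is.na(tab$p) & !is.na(tab$z)
  tab$p[miss_p] <- 2 * stats::pnorm(-abs(tab$z[miss_p]))

  ok <- !is.na(tab$snp) & !is.na(tab$a1) & !is.na(tab$a2) &
    !is.na(tab$z) & is.finite(tab$z) & !is.na(tab$n)
  n_drop <- sum(!ok)
  tab <- new_sumstats(as.data.frame(tab)[ok, , drop = FALSE],
                      trait_name = attr(tab, "trait_name"))
  if (nrow(tab) == 0) stop("no parseable rows in ", path)
  if (anyDuplicated(tab$snp)) stop("duplicated SNP ids in ", path)
  add_provenance(tab, sprintf("read %d rows from %s (%d unparseable dropped)",
                              nrow(tab), path, n_drop))
}

#' Write GWAS summary statistics
#'
#' Writes the canonical tab-delimited format with header
#' `SNP CHR BP A1 A2 MAF BETA SE Z P N INFO`; missing values are written as
#' `NA`. Round-trips losslessly through [read_sumstats()].
#'
#' @param table a `sumstats` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  if (nrow(table) == 0) stop("refusing to write an empty sumstats table")
  out <- as.data.frame(table)
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "MAF", "BETA", "SE", "Z",
                  "P", "N", "INFO")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

STRAND_AMBIGUOUS <- c("AT", "TA", "CG", "GC")

#' Filter and allele-align summary statistics against a reference
#'
#' Applies the standard pre-LDSC munging steps: removes SNPs with
#' imputation quality `info <= info_min` or reference-panel minor allele
#' frequency `maf <= maf_min`, removes strand-ambiguous (A/T, C/G) SNPs,
#' and aligns effect alleles to the reference — SNPs whose a1/a2 are
#' swapped relative to the reference have `z` and `beta` sign-flipped;
#' SNPs whose alleles match neither orientation are removed. The reference
#' MAF replaces the study MAF in the output. Removal counts per filter are
#' recorded in the provenance log. The operation is idempotent.
#'
#' @param table a `sumstats` data.frame.
#' @param ref allele/frequency reference: a data.frame with columns
#'   `snp, a1, a2, maf` (a `sumstats` table works).
#' @param info_min info filter threshold; SNPs with `info <= info_min` are
#'   removed (missing info is treated as passing). Default 0.6.
#' @param maf_min MAF filter threshold on the reference frequency; SNPs
#'   with `maf <= maf_min` are removed. Default 0.01.
#' @return filtered, allele-aligned `sumstats` data.frame.
#' @export
munge <- function(table, ref, info_min = 0.6, maf_min = 0.01) {
  stopifnot(all(c("snp", "a1", "a2", "maf") %in% names(ref)))
  n0 <- nrow(table)
  df <- as.data.frame(table)

  m <- match(df$snp, ref$snp)
  in_ref <- !is.na(m)
  n_noref <- sum(!in_ref)
  df <- df[in_ref, , drop = FALSE]
  m <- m[in_ref]

  drop_info <- !is.na(df$info) & df$info <= info_min
  ref_maf <- pmin(ref$maf[m], 1 - ref$maf[m])
  drop_maf <- is.na(ref_maf) | ref_maf <= maf_min
  drop_amb <- paste0(df$a1, df$a2) %in% STRAND_AMBIGUOUS

  ra1 <- toupper(ref$a1[m]); ra2 <- toupper(ref$a2[m])
  same <- df$a1 == ra1 & df$a2 == ra2
  swap <- df$a1 == ra2 & df$a2 == ra1
  drop_mismatch <- !(same | swap)

  keep <- !(drop_info | drop_maf | drop_amb | drop_mismatch)
  ## a SNP failing several filters is attributed to the first listed one,
  ## so |input| = |output| + sum(counts) holds exactly
  counts <- c(not_in_reference = n_noref,
              info = sum(drop_info),
              maf = sum(drop_maf & !drop_info),
              strand_ambiguous = sum(drop_amb & !drop_info & !drop_maf),
              allele_mismatch = sum(drop_mismatch & !drop_info & !drop_maf &
                                      !drop_amb))

  df <- df[keep, , drop = FALSE]
  m <- m[keep]
  sw <- swap[keep]
  if (any(sw)) {
    tmp <- df$a1[sw]; df$a1[sw] <- df$a2[sw]; df$a2[sw] <- tmp
    df$z[sw] <- -df$z[sw]
    df$beta[sw] <- -df$beta[sw]
  }
  df$maf <- pmin(ref$maf[m], 1 - ref$maf[m])

  if (nrow(df) == 0)
    stop("no SNPs survive munging; removal counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  out <- new_sumstats(df, trait_name = attr(table, "trait_name"),
                      provenance = attr(table, "provenance"))
  add_provenance(out, sprintf(
    "munge: %d -> %d SNPs (removed %s; flipped %d to reference orientation)",
    n0, nrow(out), paste(names(counts), counts, sep = "=", collapse = ", "),
    sum(sw)))
}

#' Subset summary statistics by chromosome parity
#'
#' Retains SNPs on odd- or even-numbered autosomes; `parity = "all"` is the
#' identity. An empty result is allowed and flagged in the provenance log.
#'
#' @param table a `sumstats` data.frame.
#' @param parity one of `"odd"`, `"even"`, `"all"`.
#' @return `sumstats` data.frame restricted to the requested chromosomes.
#' @export
select_chromosome_parity <- function(table, parity = c("odd", "even", "all")) {
  parity <- match.arg(parity)
  if (parity == "all") return(table)
  want <- if (parity == "odd") 1L else 0L
  keep <- !is.na(table$chr) & table$chr %% 2 == want
  out <- new_sumstats(as.data.frame(table)[keep, , drop = FALSE],
                      trait_name = attr(table, "trait_name"),
                      provenance = attr(table, "provenance"))
  out <- add_provenance(out, sprintf("parity=%s: %d -> %d SNPs",
                                     parity, nrow(table), nrow(out)))
  if (nrow(out) == 0)
    out <- add_provenance(out, sprintf("warning: no %s-chromosome SNPs",
                                       parity))
  out
}

#' Read LD-score tables
#'
#' Reads per-chromosome LD-score files (tab-delimited, header
#' `CHR SNP BP L2`) and their companion single-number M files, summing M
#' across chromosomes.
#'
#' @param ld_paths character vector of LD-score file paths.
#' @param m_paths character vector of matching M file paths; each file
#'   holds one number. When `NULL`, M defaults to the number of SNPs read.
#' @return an `ldscores` data.frame with columns `chr, snp, bp, l2` and
#'   attribute `M`.
#' @export
read_ldscores <- function(ld_paths, m_paths = NULL) {
  tabs <- lapply(ld_paths, function(p) {
    df <- utils::read.table(p, header = TRUE, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    stopifnot(all(c("chr", "snp", "bp", "l2") %in% names(df)))
    df[c("chr", "snp", "bp", "l2")]
  })
  df <- do.call(rbind, tabs)
  df <- df[order(df$chr, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  M <- if (is.null(m_paths)) nrow(df) else
    sum(vapply(m_paths, function(p) scan(p, quiet = TRUE)[1], numeric(1)))
  if (M < nrow(df) - 1e-6)
    stop("M smaller than the number of LD-score rows")
  if (any(df$l2 < 1 - 1e-6))
    warning("LD scores below 1 found (a SNP is in LD with itself)")
  new_ldscores(df, M)
}

new_ldscores <- function(df, M, blocks = NULL) {
  structure(df, class = c("ldscores", "data.frame"), M = M, blocks = blocks)
}

#' Write LD-score tables
#'
#' Writes one `CHR SNP BP L2` file and one companion M file per
#' chromosome, the on-disk layout [read_ldscores()] expects.
#'
#' @param ld an `ldscores` data.frame.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of the LD-score file paths, invisibly.
#' @export
write_ldscores <- function(ld, dir, prefix = "ld") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- attr(ld, "M")
  chroms <- sort(unique(ld$chr))
  m_per <- M / length(chroms)
  paths <- character(0)
  for (chrom in chroms) {
    sub <- as.data.frame(ld)[ld$chr == chrom, c("chr", "snp", "bp", "l2")]
    names(sub) <- c("CHR", "SNP", "BP", "L2")
    p <- file.path(dir, sprintf("%s.%d.l2.ldscore", prefix, chrom))
    utils::write.table(sub, p, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("%.10g", m_per),
               file.path(dir, sprintf("%s.%d.l2.M", prefix, chrom)))
    paths <- c(paths, p)
  }
  invisible(paths)
}
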