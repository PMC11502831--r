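# Shared fixtures, built once per test run.

# a small sumstats data.frame builder
make_sumstats <- function(n = 10, chr = NULL, z = NULL, seed = 1,
                          trait_name = "toy") {
  set.seed(seed)
  chr <- chr %||% rep(seq_len(min(n, 22)), length.out = n)
  z <- z %||% stats::rnorm(n)
  maf <- stats::runif(n, 0.05, 0.5)
  se <- 1 / sqrt(2 * maf * (1 - maf) * 10000)
  gibnet:::new_sumstats(
    data.frame(snp = sprintf("rs%04d", seq_len(n)), chr = chr,
               bp = seq_len(n) * 1000, a1 = "A", a2 = "G", maf = maf,
               beta = z * se, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), n = 10000, info = 1),
    trait_name = trait_name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one moderately sized covariance-mode study shared across test files
.shared <- new.env()
shared_study <- function() {
  if (is.null(.shared$study))
    .shared$study <- simulate_sumstats(
      truth_params(m = 20000, n_ld_blocks = 40, seed = 42))
  .shared$study
}
shared_covstruct <- function(parity = "all") {
  key <- paste0("gs_", parity)
  if (is.null(.shared[[key]])) {
    st <- shared_study()
    tabs <- if (parity == "all") st$tables else
      lapply(st$tables, select_chromosome_parity, parity = parity)
    .shared[[key]] <- build_covariance_structure(tabs, st$ld, n_blocks = 200)
  }
  .shared[[key]]
}
shared_std <- function(parity = "all") {
  key <- paste0("std_", parity)
  if (is.null(.shared[[key]]))
    .shared[[key]] <-
      smooth_structure(standardize_structure(shared_covstruct(parity)))
  .shared[[key]]
}

true_spec <- function(p = 8) {
  half <- ceiling(p / 2)
  cfa_spec(data.frame(region = sprintf("trait%02d", seq_len(p)),
                      factor = rep(c("F1", "F2"), c(half, p - half))))
}
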