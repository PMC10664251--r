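# Shared fixture builders: everything is generated in code at test time.

# a small valid summary-stats data.frame
make_records <- function(n = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ea <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  oa <- vapply(ea, function(a) {
    sample(setdiff(c("A", "C", "G", "T"),
                   c(a, c(A = "T", C = "G", G = "C", T = "A")[[a]])), 1L)
  }, character(1))
  data.frame(
    snp_id = paste0("rs", seq_len(n)),
    chrom = as.character(rep_len(1:22, n)),
    pos = 1e6 + seq_len(n) * 1e4,
    effect_allele = ea, other_allele = oa,
    eaf = runif(n, 0.05, 0.5),
    beta = rnorm(n, 0, 0.05),
    se = runif(n, 0.005, 0.02),
    pvalue = runif(n),
    n = rep(20000L, n),
    stringsAsFactors = FALSE)
}

# harmonized table built directly from numeric vectors (alleles already
# aligned), for estimator unit tests
make_tab <- function(beta_exp, se_exp, beta_out, se_out,
                     eaf = rep(0.3, length(beta_exp)),
                     n_exp = 38602, n_out = 18340,
                     outcome_type = "continuous") {
  k <- length(beta_exp)
  df <- data.frame(
    snp_id = paste0("rs", seq_len(k)), chrom = "1", pos = 1e6 + seq_len(k),
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf, n_exp = n_exp,
    pvalue_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    beta_out = beta_out, se_out = se_out, eaf_out = eaf, n_out = n_out,
    palindromic = FALSE, dropped = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE)
  structure(df, class = c("mr_harmonized", "data.frame"),
            exposure_name = "exposure", outcome_name = "outcome",
            outcome_type = outcome_type)
}

# noisy table with known slope for regression-oracle tests
make_noisy_tab <- function(k = 10, theta = 0.4, intercept = 0, seed = 1,
                           noise = 0.01) {
  set.seed(seed)
  x <- runif(k, 0.05, 0.3)
  sx <- runif(k, 0.005, 0.02)
  sy <- runif(k, 0.008, 0.03)
  y <- intercept + theta * x + rnorm(k, 0, noise)
  make_tab(x, sx, y, sy)
}

# weighted least squares through the normal equations: the independent
# oracle for IVW/Egger/MVMR regressions
wls_oracle <- function(X, y, w) {
  xtx <- t(X) %*% (w * X)
  drop(solve(xtx, t(X) %*% (w * y)))
}

# the small-panel generator configuration used across simulation tests
test_config <- function(...) {
  generator_config(n_snps = 200, ld_block_size = 5, n_instruments = 12, ...)
}

# strong-instrument configuration for consistency/recovery checks
recovery_config <- function(...) {
  test_config(instrument_z_range = c(15, 30), ...)
}

# run the univariable pipeline on a generated pair up to harmonization
select_and_harmonize <- function(pair, ...) {
  inst <- select_instruments(pair$exposure, pair$ld, ...)
  steiger_filter(harmonize(inst, pair$outcome))$table
}

# as above but without the Steiger step (for directionality tests)
select_and_harmonize_raw <- function(pair, ...) {
  harmonize(select_instruments(pair$exposure, pair$ld, ...), pair$outcome)
}
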