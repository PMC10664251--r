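# Instrument selection: significance and MAF filters, greedy LD
# clumping, instrument-strength statistics, and Steiger directionality
# filtering.

#' Filter a summary-statistics set by p-value
#'
#' Retains records with `pvalue < threshold` (strict inequality).  The
#' conventional screen starts at genome-wide significance (5e-8) and is
#' relaxed to 5e-6 when too few instruments survive clumping; see
#' [select_instruments()] for that two-stage protocol.
#'
#' @param set a [summary_stats()] object.
#' @param threshold significance threshold in (0, 1).
#' @return the filtered set, with its selection audit extended.
#' @export
filter_by_pvalue <- function(set, threshold) {
  stopifnot(inherits(set, "mr_sumstats"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  keep <- !is.na(set$pvalue) & set$pvalue < threshold
  .ss_update(set, as.data.frame(set)[keep, , drop = FALSE],
             sprintf("pvalue<%.3g", threshold))
}

#' Filter a summary-statistics set by minor-allele frequency
#'
#' Retains records whose minor-allele frequency `min(eaf, 1 - eaf)` is at
#' least `maf_min`.  Records with missing allele frequency cannot be
#' assessed and are dropped with a warning.
#'
#' @param set a [summary_stats()] object.
#' @param maf_min minimum minor-allele frequency, in [0, 0.5).
#' @return the filtered set, with its selection audit extended.
#' @export
filter_by_maf <- function(set, maf_min = 0.01) {
  stopifnot(inherits(set, "mr_sumstats"),
            is.numeric(maf_min), maf_min >= 0, maf_min < 0.5)
  maf <- pmin(set$eaf, 1 - set$eaf)
  no_eaf <- is.na(maf)
  if (any(no_eaf)) {
    warning(sum(no_eaf), " record(s) dropped for missing eaf (reason no_eaf)")
  }
  keep <- !no_eaf & maf >= maf_min
  .ss_update(set, as.data.frame(set)[keep, , drop = FALSE],
             sprintf("maf>=%.3g", maf_min))
}

# r2 lookup for a set of SNP ids; unrecorded pairs are 0
.ld_lookup <- function(ld, ids) {
  p <- ld$pairs[ld$pairs$snp_id_a %in% ids & ld$pairs$snp_id_b %in% ids, ,
                drop = FALSE]
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(2L * nrow(p), 29L))
  if (nrow(p) > 0L) {
    for (i in seq_len(nrow(p))) {
      assign(paste(p$snp_id_a[i], p$snp_id_b[i], sep = "\r"), p$r2[i], envir = env)
      assign(paste(p$snp_id_b[i], p$snp_id_a[i], sep = "\r"), p$r2[i], envir = env)
    }
  }
  function(a, b) {
    if (a == b) return(1)
    v <- get0(paste(a, b, sep = "\r"), envir = env, ifnotfound = 0)
    v
  }
}

#' Greedy LD clumping
#'
#' Repeatedly takes the most significant unclaimed SNP as an index SNP
#' (ties broken by chromosome, position, then SNP id) and removes every
#' unclaimed SNP on the same chromosome within `window_kb` of it whose
#' r-squared with the index reaches `r2_max`.  SNP pairs absent from the
#' LD reference are treated as independent (r-squared 0); SNPs on
#' different chromosomes never clump.
#'
#' @param set a [summary_stats()] object.
#' @param ld an [ld_reference()] whose position map covers every SNP in
#'   `set` (a missing SNP is an error).
#' @param r2_max r-squared at or above which two SNPs are clumped
#'   (default 0.001).
#' @param window_kb clumping distance in kilobases (default 10000).
#' @return the set of index SNPs, audit extended with step `ld_clump`.
#' @export
ld_clump <- function(set, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(set, "mr_sumstats"), inherits(ld, "mr_ld"),
            r2_max > 0, window_kb >= 0)
  if (nrow(set) == 0L) return(.ss_update(set, as.data.frame(set), "ld_clump"))
  pos_idx <- match(set$snp_id, ld$positions$snp_id)
  if (anyNA(pos_idx)) {
    stop("SNP(s) missing from LD position map: ",
         paste(utils::head(set$snp_id[is.na(pos_idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  chrom <- ld$positions$chrom[pos_idx]
  pos <- ld$positions$pos[pos_idx]
  r2 <- .ld_lookup(ld, set$snp_id)

  ord <- order(set$pvalue, .chrom_rank(chrom), pos, set$snp_id)
  claimed <- rep(FALSE, nrow(set))
  index <- logical(nrow(set))
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    index[i] <- TRUE
    near <- which(!claimed & chrom == chrom[i] &
                    abs(pos - pos[i]) <= window_bp)
    for (j in near) {
      if (r2(set$snp_id[i], set$snp_id[j]) >= r2_max) claimed[j] <- TRUE
    }
  }
  .ss_update(set, as.data.frame(set)[index, , drop = FALSE], "ld_clump")
}

#' Variance in a trait explained by one SNP
#'
#' Computes, from summary-level quantities alone,
#' \deqn{R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
#'   {2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
#'    2\,\mathrm{EAF}(1-\mathrm{EAF})\,N\,\mathrm{SE}(\beta)^2},}
#' the proportion of trait variance attributable to the variant.  The
#' allele-frequency factor cancels algebraically, so the value reduces to
#' `beta^2 / (beta^2 + n * se^2)`; the full expression is evaluated as
#' printed.  Vectorized over all arguments.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param beta per-allele effect estimate.
#' @param se standard error of `beta`, > 0.
#' @param n GWAS sample size, >= 3.
#' @return variance explained, in [0, 1).
#' @export
variance_explained <- function(eaf, beta, se, n) {
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    stop("eaf must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(all(se > 0, na.rm = TRUE), all(n >= 3, na.rm = TRUE))
  g <- 2 * eaf * (1 - eaf)
  (g * beta^2) / (g * beta^2 + g * n * se^2)
}

#' Instrument-strength F-statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)`, the single-instrument F-statistic from
#' the variance explained and the GWAS sample size.  Instruments with
#' F at or below 10 are conventionally considered weak and removed.
#'
#' @param r2 variance explained, in [0, 1).
#' @param n GWAS sample size, >= 3.
#' @return F-statistic, >= 0; monotone in both arguments.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 >= 1 | r2 < 0, na.rm = TRUE)) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(all(n >= 3, na.rm = TRUE))
  r2 * (n - 2) / (1 - r2)
}

#' Select instruments with the full two-stage screening protocol
#'
#' Applies, in order: a significance filter at genome-wide significance
#' (`pval_strict`), the minor-allele-frequency filter, LD clumping, and
#' the F > `min_f` strength filter.  If fewer than `min_instruments`
#' SNPs survive clumping at the strict threshold, the whole screen is
#' repeated at the relaxed threshold `pval` — the usual fallback when a
#' trait (most microbial taxa among them) has no genome-wide significant
#' hits.
#'
#' @param set exposure [summary_stats()].
#' @param ld an [ld_reference()].
#' @param pval relaxed significance threshold (default 5e-6).
#' @param pval_strict first-stage genome-wide threshold (default 5e-8).
#' @param maf_min minor-allele-frequency cutoff (default 0.01).
#' @param r2_max,window_kb clumping parameters (defaults 0.001, 10000).
#' @param min_f weak-instrument cutoff; SNPs with F-statistic at or below
#'   this are removed (default 10).
#' @param min_instruments minimum count that must survive clumping at the
#'   strict threshold before the relaxed stage is skipped (default 3).
#' @param two_stage set `FALSE` to screen at `pval` only.
#' @return the selected instruments with per-SNP `r2_trait` and `f_stat`
#'   columns and a complete audit (`attr(x, "audit")`).
#' @export
select_instruments <- function(set, ld, pval = 5e-6, pval_strict = 5e-8,
                               maf_min = 0.01, r2_max = 0.001,
                               window_kb = 10000, min_f = 10,
                               min_instruments = 3, two_stage = TRUE) {
  run_stage <- function(threshold) {
    s <- filter_by_pvalue(set, threshold)
    s <- filter_by_maf(s, maf_min)
    ld_clump(s, ld, r2_max = r2_max, window_kb = window_kb)
  }
  out <- if (two_stage) {
    strict <- run_stage(pval_strict)
    if (nrow(strict) >= min_instruments) strict else run_stage(pval)
  } else {
    run_stage(pval)
  }
  if (nrow(out) == 0L) {
    out$r2_trait <- numeric(0)
    out$f_stat <- numeric(0)
    return(out)
  }
  r2 <- variance_explained(out$eaf, out$beta, out$se, out$n)
  f <- f_statistic(r2, out$n)
  df <- as.data.frame(out)
  df$r2_trait <- r2
  df$f_stat <- f
  .ss_update(out, df[f > min_f, , drop = FALSE],
             sprintf("f_stat>%.3g", min_f))
}

#' Steiger directionality filtering
#'
#' For each retained instrument, compares the variance it explains in the
#' exposure with the variance it explains in the outcome (both via
#' [variance_explained()]).  A verdict of `TRUE` — exposure r-squared
#' greater than outcome r-squared — supports the assumed causal
#' direction; `FALSE` rows are excluded from the returned table (reason
#' `"steiger_false"`).  Rows lacking allele frequency or sample size on
#' either side cannot be tested: they pass with a warning and are
#' recorded as untestable.
#'
#' An optional z-test variant (`use_z_test = TRUE`) only fails a SNP when
#' the outcome r-squared significantly exceeds the exposure r-squared
#' (Fisher z comparison of the implied correlations at `alpha`); the
#' default is the plain r-squared comparison.
#'
#' @param table an `mr_harmonized` table.
#' @param use_z_test use the significance-aware variant.
#' @param alpha one-sided level for the z-test variant.
#' @return `list(table = , verdicts = )`: the filtered table and a
#'   data.frame of per-SNP verdicts (`snp_id`, `r2_exposure`,
#'   `r2_outcome`, `verdict`, `untestable`).
#' @export
steiger_filter <- function(table, use_z_test = FALSE, alpha = 0.05) {
  stopifnot(inherits(table, "mr_harmonized"))
  keep <- which(!table$dropped)
  if (length(keep) == 0L) {
    return(list(table = table,
                verdicts = data.frame(snp_id = character(0),
                                      r2_exposure = numeric(0),
                                      r2_outcome = numeric(0),
                                      verdict = logical(0),
                                      untestable = logical(0))))
  }
  r <- table[keep, , drop = FALSE]
  untestable <- is.na(r$eaf_exp) | is.na(r$n_exp) |
    is.na(r$eaf_out) | is.na(r$n_out)
  r2e <- r2o <- rep(NA_real_, nrow(r))
  t <- !untestable
  r2e[t] <- variance_explained(r$eaf_exp[t], r$beta_exp[t], r$se_exp[t], r$n_exp[t])
  r2o[t] <- variance_explained(r$eaf_out[t], r$beta_out[t], r$se_out[t], r$n_out[t])
  verdict <- rep(TRUE, nrow(r))
  if (use_z_test) {
    z <- (atanh(sqrt(r2o[t])) - atanh(sqrt(r2e[t]))) /
      sqrt(1 / (r$n_exp[t] - 3) + 1 / (r$n_out[t] - 3))
    verdict[t] <- stats::pnorm(z, lower.tail = FALSE) > alpha
  } else {
    verdict[t] <- r2e[t] > r2o[t]
  }
  if (any(untestable)) {
    warning(sum(untestable),
            " SNP(s) lacked eaf or n on one side; passed as untestable")
  }
  fail <- keep[!verdict]
  table$dropped[fail] <- TRUE
  table$reason[fail] <- "steiger_false"
  list(table = table,
       verdicts = data.frame(snp_id = r$snp_id, r2_exposure = r2e,
                             r2_outcome = r2o, verdict = verdict,
                             untestable = untestable,
                             stringsAsFactors = FALSE))
}
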