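# Bidirectional many-taxa screening: multiplicity rules, per-pair
# orchestration, and result export.

.TAXON_LEVELS <- c("phylum", "class", "order", "family", "genus")

#' Bonferroni threshold for one taxonomic level
#'
#' `0.05 / n`, where n is the number of independent bacterial taxa
#' analyzed at that level.  With the usual microbiota panel this gives,
#' e.g., 3.125e-3 for 16 classes and 3.906e-4 for 128 genera.
#'
#' @param n_taxa_at_level number of taxa analyzed at the level, >= 1.
#' @return the per-level significance threshold.
#' @export
bonferroni_threshold <- function(n_taxa_at_level) {
  if (any(n_taxa_at_level < 1)) stop("n must be >= 1", call. = FALSE)
  0.05 / n_taxa_at_level
}

#' Classify a p-value against a level threshold
#'
#' `significant` below the multiple-testing threshold;
#' `potentially_significant` between the threshold and the nominal 0.05;
#' `not_significant` otherwise.  Vectorized over `p`.
#'
#' @param p p-value(s) in (0, 1].
#' @param level_threshold the level's Bonferroni threshold, <= 0.05.
#' @return character vector of significance classes.
#' @export
classify_significance <- function(p, level_threshold) {
  stopifnot(all(level_threshold <= 0.05), all(level_threshold > 0))
  ifelse(is.na(p), "not_estimable",
         ifelse(p < level_threshold, "significant",
                ifelse(p < 0.05, "potentially_significant",
                       "not_significant")))
}

#' Construct a taxa manifest
#'
#' The bookkeeping table of a microbiota screening panel: taxon names
#' and their taxonomic levels (plus an optional file reference per
#' taxon).  Per-level counts drive the Bonferroni thresholds.
#'
#' @param taxon character vector of unique taxon names.
#' @param level matching vector of levels (phylum/class/order/family/
#'   genus).
#' @param file optional per-taxon summary-statistics file reference.
#' @return data.frame of class `taxa_manifest`.
#' @export
taxa_manifest <- function(taxon, level, file = NA_character_) {
  stopifnot(!anyDuplicated(taxon), all(level %in% .TAXON_LEVELS))
  structure(data.frame(taxon = as.character(taxon),
                       level = as.character(level),
                       file = file, stringsAsFactors = FALSE),
            class = c("taxa_manifest", "data.frame"))
}

#' FTND severity composition of the nicotine-dependence GWAS cohort
#'
#' Reference counts of the Fagerström Test for Nicotine Dependence
#' severity strata in the dependence GWAS meta-analysis this package's
#' defaults are sized for (38,602 former smokers).  Useful for
#' sample-composition sanity checks and for documenting what the
#' synthetic sample sizes emulate.
#'
#' @return data.frame with columns `severity`, `n`, `percent` (percent
#'   computed from the counts).
#' @export
ftnd_cohort_composition <- function() {
  counts <- c(mild = 17796L, moderate = 13527L, severe = 7279L)
  data.frame(severity = names(counts), n = as.integer(counts),
             percent = 100 * as.integer(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

#' Default screening configuration
#'
#' Every tunable of the screening pipeline with its default: strict and
#' relaxed instrument p-value thresholds (5e-8, 5e-6), MAF cutoff
#' (0.01), clumping r-squared and window (0.001, 10000 kb), minimum
#' F-statistic (10), minimum instrument count before threshold
#' relaxation (3), nominal alpha (0.05), palindrome policy, MR-PRESSO
#' simulation count and outlier level, and bootstrap size for the
#' median/mode estimators.
#'
#' @param ... overrides for any default.
#' @return a named list of class `mr_config`.
#' @export
mr_config <- function(...) {
  cfg <- list(pval = 5e-6, pval_strict = 5e-8, maf_min = 0.01,
              clump_r2 = 0.001, clump_kb = 10000, min_f = 10,
              min_instruments = 3, alpha = 0.05,
              palindrome_policy = "drop_ambiguous",
              presso_n_sim = 1000, presso_sig = 0.05,
              n_boot = 1000, seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(override)] <- override
  structure(cfg, class = "mr_config")
}

# run one exposure-outcome pair end to end; never throws
.run_pair <- function(exposure, outcome, ld, config, seed) {
  tryCatch({
    inst <- select_instruments(exposure, ld,
                               pval = config$pval,
                               pval_strict = config$pval_strict,
                               maf_min = config$maf_min,
                               r2_max = config$clump_r2,
                               window_kb = config$clump_kb,
                               min_f = config$min_f,
                               min_instruments = config$min_instruments)
    if (nrow(inst) == 0L) {
      return(list(status = "not_estimable", reason = "no_instruments"))
    }
    tab <- harmonize(inst, outcome,
                     palindrome_policy = config$palindrome_policy)
    st <- steiger_filter(tab)
    tab <- st$table
    k <- nrow(retained(tab))
    if (k == 0L) {
      return(list(status = "not_estimable", reason = "no_harmonized_snps"))
    }
    estimates <- run_all_methods(tab, n_boot = config$n_boot, seed = seed)
    sens <- sensitivity_report(tab, n_sim = config$presso_n_sim,
                               outlier_sig = config$presso_sig, seed = seed)
    original_estimates <- NULL
    if (sens$presso$estimable && length(sens$presso$outlier_snps) > 0L) {
      # outlier-corrected estimates replace the headline table; the
      # uncorrected run stays available in the sensitivity bundle
      original_estimates <- estimates
      out_rows <- tab$snp_id %in% sens$presso$outlier_snps & !tab$dropped
      tab$dropped[out_rows] <- TRUE
      tab$reason[out_rows] <- "presso_outlier"
      estimates <- run_all_methods(tab, n_boot = config$n_boot, seed = seed)
    }
    list(status = "estimable", n_snp = nrow(retained(tab)),
         estimates = estimates, sensitivity = sens,
         steiger = st$verdicts, original_estimates = original_estimates,
         audit = attr(inst, "audit"))
  }, error = function(e) {
    list(status = "not_estimable", reason = conditionMessage(e))
  })
}

#' Run one direction of the bidirectional screen
#'
#' For every taxon in the manifest, runs the full per-pair workflow:
#' instrument selection (two-stage threshold, MAF, clumping, F filter),
#' harmonization, Steiger filtering, the five-estimator battery, the
#' sensitivity suite including MR-PRESSO (with outlier-corrected
#' re-estimation when outliers are found), and classification of the
#' IVW p-value against the level's Bonferroni threshold.  The threshold
#' denominator is the number of *estimable* taxa at each level in this
#' run, so it adapts to data loss exactly as the screening convention
#' requires.  Per-pair failures are isolated: the batch always
#' completes, with failed pairs recorded `not_estimable` and a reason.
#'
#' @param exposure_sets for `direction = "forward"`, a single
#'   [summary_stats()] (the trait); for `"reverse"`, a named list of
#'   per-taxon sets.
#' @param outcome_sets the complementary side: a named list of
#'   per-taxon sets (forward) or a single trait set (reverse).
#' @param manifest a [taxa_manifest()]; taxa without a matching set are
#'   reported `not_estimable` with reason `"missing_data"`.
#' @param ld an [ld_reference()] covering the instrument candidates.
#' @param config an [mr_config()].
#' @param direction `"forward"` (trait -> taxa) or `"reverse"`.
#' @return an object of class `mr_screen`: list with `direction`,
#'   `summary` (one row per taxon: status, n_snp, IVW estimate and
#'   p-value, level threshold, significance class), `estimates` (long
#'   table, one row per taxon x method), and `details` (per-taxon
#'   sensitivity bundles).
#' @export
run_direction <- function(exposure_sets, outcome_sets, manifest, ld,
                          config = mr_config(),
                          direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(manifest, "taxa_manifest"))
  taxa_side <- if (direction == "forward") outcome_sets else exposure_sets
  stopifnot(is.list(taxa_side), !is.null(names(taxa_side)))

  results <- vector("list", nrow(manifest))
  names(results) <- manifest$taxon
  for (i in seq_len(nrow(manifest))) {
    taxon <- manifest$taxon[i]
    if (!taxon %in% names(taxa_side)) {
      results[[i]] <- list(status = "not_estimable", reason = "missing_data")
      next
    }
    pair_seed <- config$seed + i
    results[[i]] <- if (direction == "forward") {
      .run_pair(exposure_sets, taxa_side[[taxon]], ld, config, pair_seed)
    } else {
      .run_pair(taxa_side[[taxon]], outcome_sets, ld, config, pair_seed)
    }
  }

  estimable <- vapply(results, function(r) r$status == "estimable", logical(1L))
  n_level <- table(factor(manifest$level[estimable], levels = .TAXON_LEVELS))
  cnt <- as.integer(n_level[manifest$level])
  thresholds <- rep(NA_real_, nrow(manifest))
  thresholds[cnt > 0] <- bonferroni_threshold(cnt[cnt > 0])

  ivw_beta <- ivw_p <- rep(NA_real_, nrow(manifest))
  n_snp <- rep(NA_integer_, nrow(manifest))
  reason <- rep(NA_character_, nrow(manifest))
  est_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- results[[i]]
    if (r$status == "estimable") {
      ivw <- r$estimates[1L, ]
      ivw_beta[i] <- ivw$beta
      ivw_p[i] <- ivw$pvalue
      n_snp[i] <- r$n_snp
      e <- as.data.frame(r$estimates)
      e$taxon <- manifest$taxon[i]
      e$level <- manifest$level[i]
      est_rows[[length(est_rows) + 1L]] <- e
    } else {
      reason[i] <- r$reason
    }
  }
  sig_class <- rep("not_estimable", nrow(manifest))
  sig_class[estimable] <- classify_significance(ivw_p[estimable],
                                                thresholds[estimable])
  summary <- data.frame(taxon = manifest$taxon, level = manifest$level,
                        status = ifelse(estimable, "estimable",
                                        "not_estimable"),
                        reason = reason, n_snp = n_snp,
                        ivw_beta = ivw_beta, ivw_p = ivw_p,
                        level_threshold = thresholds,
                        significance_class = sig_class,
                        stringsAsFactors = FALSE)
  estimates <- if (length(est_rows) > 0L) do.call(rbind, est_rows) else
    data.frame()
  structure(list(direction = direction, summary = summary,
                 estimates = estimates, details = results,
                 config = config),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  tab <- table(x$summary$significance_class)
  cat(sprintf("<mr_screen> direction %s: %d taxa (%s)\n", x$direction,
              nrow(x$summary),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export screen results to disk
#'
#' Writes, under `out_dir`: `estimates_<direction>.tsv` (one row per
#' taxon x method, forest-plot-ready), `summary_<direction>.tsv` (one
#' row per taxon with significance class), and
#' `sensitivity_<direction>.json` (per-taxon heterogeneity, Egger
#' intercept, leave-one-out, funnel and MR-PRESSO bundles).  An empty
#' result produces header-only tables with a warning.
#'
#' @param result an `mr_screen` from [run_direction()].
#' @param out_dir output directory, created if absent.
#' @return character vector of the files written, invisibly.
#' @export
export_results <- function(result, out_dir) {
  stopifnot(inherits(result, "mr_screen"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  d <- result$direction
  est_path <- file.path(out_dir, paste0("estimates_", d, ".tsv"))
  sum_path <- file.path(out_dir, paste0("summary_", d, ".tsv"))
  sens_path <- file.path(out_dir, paste0("sensitivity_", d, ".json"))

  est <- result$estimates
  if (nrow(est) == 0L) {
    warning("empty screen result: writing header-only tables")
    est <- data.frame(taxon = character(0), level = character(0),
                      method = character(0), n_snp = integer(0),
                      beta = numeric(0), se = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      pvalue = numeric(0))
  } else {
    lead <- c("taxon", "level")
    est <- est[, c(lead, setdiff(names(est), lead))]
  }
  utils::write.table(est, est_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sens <- lapply(result$details, function(r) {
    if (r$status != "estimable") {
      return(list(status = r$status, reason = r$reason))
    }
    s <- r$sensitivity
    presso <- if (s$presso$estimable) {
      list(global_rss_obs = s$presso$global_rss_obs,
           global_p = s$presso$global_p,
           global_p_lt = s$presso$global_p_lt,
           outlier_snps = s$presso$outlier_snps,
           distortion_p = s$presso$distortion_p)
    } else {
      list(estimable = FALSE)
    }
    list(status = "estimable", n_snp = s$n_snp,
         q_ivw = as.list(s$q_ivw), q_egger = as.list(s$q_egger),
         egger_intercept = as.list(s$egger_intercept),
         leave_one_out = s$leave_one_out, funnel = s$funnel,
         presso = presso,
         original_estimates = if (!is.null(r$original_estimates))
           as.data.frame(r$original_estimates) else NULL)
  })
  jsonlite::write_json(sens, sens_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(est_path, sum_path, sens_path))
}
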