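# Heterogeneity, pleiotropy, leave-one-out, funnel, and MR-PRESSO
# diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' For the IVW parameterization, `Q = sum w_j (ratio_j - b_ivw)^2` with
#' `w_j = beta_exp_j^2 / se_out_j^2` (the regression-residual form and
#' the ratio form are algebraically identical); the reference
#' distribution is chi-squared with k-1 degrees of freedom.  For the
#' Egger parameterization the residuals come from the intercept model
#' and the degrees of freedom are k-2.  A significant Q is the usual
#' trigger for the multiplicative random-effects IVW model.
#'
#' @param table an `mr_harmonized` table (or its retained rows).
#' @param method `"ivw"` or `"egger"`.
#' @return named numeric vector `c(Q, df, p)`.
#' @export
cochran_q <- function(table, method = c("ivw", "egger")) {
  method <- match.arg(method)
  if (method == "ivw") {
    tab <- .retained_tab(table, 2L, "Cochran's Q (IVW)")
    est <- mr_ivw(tab, effects = "fixed", or_scale = FALSE)
    het <- attr(est, "heterogeneity")
    c(Q = unname(het["Q"]), df = unname(het["df"]), p = unname(het["p"]))
  } else {
    tab <- .retained_tab(table, 3L, "Cochran's Q (Egger)")
    e <- mr_egger(tab, or_scale = FALSE)
    c(Q = e$q, df = e$df,
      p = stats::pchisq(e$q, df = e$df, lower.tail = FALSE))
  }
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average
#' pleiotropic effect across instruments; an intercept significantly
#' different from zero indicates directional pleiotropy.  Two-sided
#' Student t test with k-2 degrees of freedom.
#'
#' @inheritParams cochran_q
#' @return named numeric vector `c(value, se, p)`.
#' @export
egger_intercept_test <- function(table) {
  e <- mr_egger(table, or_scale = FALSE)
  c(value = e$intercept, se = e$intercept_se, p = e$intercept_p)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn.  A
#' removal is flagged when it changes the sign of the estimate or moves
#' it outside the all-SNP confidence interval — machine-readable
#' versions of the visual stability check.
#'
#' @inheritParams cochran_q
#' @param effects IVW effects mode passed through to [mr_ivw()];
#'   `"fixed"` by default so the influence flag compares against the
#'   sharp (uninflated) interval — with `"auto"`, a single gross
#'   outlier inflates the random-effects interval enough to mask its
#'   own influence.
#' @return data.frame with one row per removed SNP: `snp_id_removed`,
#'   `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `flagged`.
#' @export
leave_one_out <- function(table, effects = "fixed") {
  tab <- .retained_tab(table, 3L, "leave-one-out")
  full <- mr_ivw(tab, effects = effects, or_scale = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    est <- mr_ivw(tab[-i, , drop = FALSE], effects = effects,
                  or_scale = FALSE)
    data.frame(snp_id_removed = tab$snp_id[i], n_snp = est$n_snp,
               beta = est$beta, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pvalue = est$pvalue,
               flagged = sign(est$beta) != sign(full$beta) |
                 est$beta < full$ci_low | est$beta > full$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio against its precision (the reciprocal of the
#' first-order ratio SE, `|beta_exp| / se_out`).  Asymmetry of the
#' funnel around the pooled estimate suggests directional pleiotropy;
#' this function exports the points, rendering is left to the caller.
#'
#' @inheritParams cochran_q
#' @return data.frame with columns `snp_id`, `ratio`, `precision`
#'   (empty for an empty table).
#' @export
funnel_data <- function(table) {
  tab <- if (inherits(table, "mr_harmonized")) retained(table) else table
  if (nrow(tab) == 0L) {
    return(data.frame(snp_id = character(0), ratio = numeric(0),
                      precision = numeric(0)))
  }
  r <- .ratio_stats(tab)
  data.frame(snp_id = tab$snp_id, ratio = r$ratio, precision = 1 / r$se1,
             stringsAsFactors = FALSE)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Regression-based pleiotropy diagnostics in three parts.
#'
#' 1. *Global test.*  The observed residual sum of squares is built from
#'    leave-one-out IVW predictions: each SNP's squared distance from
#'    the regression fitted without it, weighted by `1/se_out^2`.  Its
#'    null distribution is obtained by parametric simulation under the
#'    no-pleiotropy model — outcome associations redrawn as
#'    `Normal(fit_j, se_out_j)` (`n_sim` draws) — and the global p-value
#'    is the exceedance fraction.
#' 2. *Outlier test.*  Each SNP's observed squared distance is compared
#'    with its simulated distances; per-SNP p-values are
#'    Bonferroni-corrected across instruments and SNPs below
#'    `outlier_sig` are declared outliers.
#' 3. *Distortion test.*  When outliers are found, the IVW estimate is
#'    recomputed without them and the relative change is compared with a
#'    permutation-style null built by removing equally many randomly
#'    chosen non-outlier SNPs.
#'
#' Rows are processed in canonical (SNP-id) order so results are
#' invariant to input row order; with a fixed seed the whole object is
#' reproducible.  Exceedance p-values are never reported as exactly
#' zero: a count of zero becomes `1/n_sim` with the corresponding
#' `*_lt` flag set.
#'
#' @inheritParams cochran_q
#' @param n_sim simulated null datasets (default 1000).
#' @param outlier_sig significance level for the Bonferroni-corrected
#'   per-SNP outlier test (default 0.05).
#' @param seed RNG seed.
#' @return an object of class `mr_presso`: a list with `estimable`,
#'   `global_rss_obs`, `global_p`, `global_p_lt`, `outliers` (data.frame
#'   `snp_id`, `p_raw`, `p_bonferroni`, `is_outlier`), `outlier_snps`,
#'   `corrected_estimate` (IVW without outliers, or `NULL`),
#'   `distortion_coef`, `distortion_p`, `n_sim`, `seed`.  When fewer
#'   than 4 instruments are available, `estimable = FALSE` and the tests
#'   are absent.
#' @export
mr_presso <- function(table, n_sim = 1000, outlier_sig = 0.05, seed = 1) {
  tab <- if (inherits(table, "mr_harmonized")) retained(table) else table
  if (nrow(tab) < 4L) {
    return(structure(list(estimable = FALSE, n_snp = nrow(tab),
                          n_sim = n_sim, seed = seed),
                     class = "mr_presso"))
  }
  tab <- tab[order(tab$snp_id), , drop = FALSE]
  k <- nrow(tab)
  x <- tab$beta_exp; y <- tab$beta_out
  w <- 1 / tab$se_out^2

  loo_slope <- function(yv) {
    (sum(w * x * yv) - w * x * yv) / (sum(w * x^2) - w * x^2)
  }
  b_loo <- loo_slope(y)
  d_obs <- w * (y - b_loo * x)^2
  rss_obs <- sum(d_obs)

  set.seed(seed)
  ystar <- matrix(stats::rnorm(k * n_sim, mean = b_loo * x, sd = tab$se_out),
                  nrow = k)
  sxx <- sum(w * x^2)
  sxy_star <- colSums(w * x * ystar)
  b_loo_star <- (rep(sxy_star, each = k) - w * x * ystar) / (sxx - w * x^2)
  d_star <- w * (ystar - b_loo_star * x)^2
  rss_star <- colSums(d_star)

  exceed <- sum(rss_star >= rss_obs)
  global_p_lt <- exceed == 0L
  global_p <- max(exceed, 1L) / n_sim

  p_raw <- rowMeans(d_star >= d_obs)
  p_raw_lt <- p_raw == 0
  p_raw[p_raw_lt] <- 1 / n_sim
  p_bonf <- pmin(1, p_raw * k)
  is_out <- p_bonf < outlier_sig
  outliers <- data.frame(snp_id = tab$snp_id, p_raw = p_raw,
                         p_bonferroni = p_bonf, is_outlier = is_out,
                         stringsAsFactors = FALSE)

  corrected <- NULL
  distortion_coef <- NULL
  distortion_p <- NULL
  if (any(is_out) && sum(!is_out) >= 2L) {
    full <- mr_ivw(tab, effects = "fixed", or_scale = FALSE)
    corrected <- mr_ivw(tab[!is_out, , drop = FALSE], effects = "fixed",
                        or_scale = FALSE)
    distortion_coef <- 100 * (full$beta - corrected$beta) / abs(corrected$beta)
    n_out <- sum(is_out)
    keep_pool <- which(!is_out)
    if (length(keep_pool) > n_out) {
      null_dist <- vapply(seq_len(n_sim), function(i) {
        drop <- sample(keep_pool, n_out)
        bi <- mr_ivw(tab[-drop, , drop = FALSE], effects = "fixed",
                     or_scale = FALSE)$beta
        100 * (full$beta - bi) / abs(bi)
      }, numeric(1L))
      exceed_d <- sum(abs(null_dist) >= abs(distortion_coef))
      distortion_p <- max(exceed_d, 1L) / n_sim
    }
  }

  structure(list(estimable = TRUE, n_snp = k,
                 global_rss_obs = rss_obs, global_p = global_p,
                 global_p_lt = global_p_lt, outliers = outliers,
                 outlier_snps = tab$snp_id[is_out],
                 corrected_estimate = corrected,
                 distortion_coef = distortion_coef,
                 distortion_p = distortion_p,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  if (!x$estimable) {
    cat("<mr_presso> not estimable (", x$n_snp, " instrument(s), need 4)\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("<mr_presso> global RSS %.4g, p %s%.4g; %d outlier(s)\n",
              x$global_rss_obs, if (x$global_p_lt) "< " else "",
              x$global_p, length(x$outlier_snps)))
  invisible(x)
}

#' Full sensitivity report for one harmonized table
#'
#' Bundles Cochran's Q (IVW and Egger parameterizations), the Egger
#' intercept test, leave-one-out estimates, funnel data and MR-PRESSO.
#' Components whose instrument-count floor is not met are `NULL`.
#'
#' @inheritParams mr_presso
#' @return a list of class `mr_sensitivity` with elements `q_ivw`,
#'   `q_egger`, `egger_intercept`, `leave_one_out`, `funnel`, `presso`.
#' @export
sensitivity_report <- function(table, n_sim = 1000, outlier_sig = 0.05,
                               seed = 1) {
  tab <- if (inherits(table, "mr_harmonized")) retained(table) else table
  k <- nrow(tab)
  structure(list(
    n_snp = k,
    q_ivw = if (k >= 2L) cochran_q(tab, "ivw") else NULL,
    q_egger = if (k >= 3L) cochran_q(tab, "egger") else NULL,
    egger_intercept = if (k >= 3L) egger_intercept_test(tab) else NULL,
    leave_one_out = if (k >= 3L) leave_one_out(tab) else NULL,
    funnel = funnel_data(tab),
    presso = mr_presso(tab, n_sim = n_sim, outlier_sig = outlier_sig,
                       seed = seed)
  ), class = "mr_sensitivity")
}
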