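# Univariable two-sample MR estimators: Wald ratio, IVW, MR-Egger,
# weighted median, and mode-based estimators.

#' Construct an MR estimate record
#'
#' One causal estimate: method label, instrument count, effect with
#' standard error, 95% interval, and p-value.  For binary outcomes the
#' exponentiated (odds-ratio) scale is appended.
#'
#' @param method method label.
#' @param n_snp number of instruments used.
#' @param beta,se estimate and standard error on the beta scale.
#' @param df degrees of freedom for the reference distribution
#'   (`Inf` for normal, finite for Student t).
#' @param or_scale append `or`, `or_ci_low`, `or_ci_high` columns.
#' @return a one-row data.frame of class `mr_estimate`.
#' @export
mr_estimate <- function(method, n_snp, beta, se, df = Inf, or_scale = FALSE) {
  stopifnot(is.finite(beta), se >= 0)
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  p <- if (se == 0) {
    if (beta == 0) 1 else .Machine$double.xmin
  } else if (is.finite(df)) {
    2 * stats::pt(-abs(beta / se), df)
  } else {
    2 * stats::pnorm(-abs(beta / se))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  out <- data.frame(method = method, n_snp = as.integer(n_snp),
                    beta = beta, se = se,
                    ci_low = beta - crit * se, ci_high = beta + crit * se,
                    pvalue = p, stringsAsFactors = FALSE)
  if (or_scale) {
    out$or <- exp(out$beta)
    out$or_ci_low <- exp(out$ci_low)
    out$or_ci_high <- exp(out$ci_high)
  }
  class(out) <- c("mr_estimate", "data.frame")
  out
}

.not_estimable <- function(method, n_snp, or_scale = FALSE) {
  out <- data.frame(method = method, n_snp = as.integer(n_snp),
                    beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, pvalue = NA_real_,
                    stringsAsFactors = FALSE)
  if (or_scale) out$or <- out$or_ci_low <- out$or_ci_high <- NA_real_
  class(out) <- c("mr_estimate", "data.frame")
  out
}

# per-SNP Wald ratios with first- and second-order delta-method SEs
.ratio_stats <- function(tab) {
  x <- tab$beta_exp; y <- tab$beta_out
  if (any(x == 0)) stop("zero exposure effect: Wald ratio undefined",
                        call. = FALSE)
  ratio <- y / x
  se1 <- tab$se_out / abs(x)
  se2 <- sqrt(tab$se_out^2 / x^2 + y^2 * tab$se_exp^2 / x^4)
  list(x = x, y = y, ratio = ratio, se1 = se1, se2 = se2,
       w_out = 1 / tab$se_out^2)
}

.retained_tab <- function(table, min_snp, what) {
  tab <- if (inherits(table, "mr_harmonized")) retained(table) else table
  if (nrow(tab) < min_snp) {
    stop("insufficient instruments for ", what, ": have ", nrow(tab),
         ", need >= ", min_snp, call. = FALSE)
  }
  tab
}

.is_binary_outcome <- function(table) {
  identical(attr(table, "outcome_type"), "binary")
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome association divided by
#' the SNP-exposure association.  The default standard error is the
#' first-order delta-method value `se_out / |beta_exp|`; the
#' second-order variant additionally propagates the exposure uncertainty.
#'
#' @param beta_exp,se_exp SNP-exposure association and its SE.
#' @param beta_out,se_out SNP-outcome association and its SE.
#' @param second_order use the second-order delta-method SE.
#' @param or_scale report the odds-ratio scale as well.
#' @return an [mr_estimate()] with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE, or_scale = FALSE) {
  if (beta_exp == 0) stop("beta_exp = 0: Wald ratio undefined", call. = FALSE)
  est <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  mr_estimate("wald_ratio", 1L, est, se, or_scale = or_scale)
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analysis of the per-variant Wald ratios, computed as the
#' weighted regression of the outcome associations on the exposure
#' associations through the origin with weights `1/se_out^2`.  The
#' fixed-effects standard error forces the residual variance to one; the
#' (multiplicative) random-effects model inflates it by
#' `sqrt(max(1, Q/(k-1)))`, where Q is Cochran's heterogeneity
#' statistic.  With `effects = "auto"` the random-effects inflation is
#' applied when the heterogeneity test rejects at `q_alpha`, mirroring
#' common screening practice.  A single instrument degenerates to its
#' Wald ratio, labelled `ivw_fixed`.
#'
#' @param table an `mr_harmonized` table (or its retained rows).
#' @param effects `"fixed"`, `"random"`, or `"auto"`.
#' @param q_alpha heterogeneity level driving the `"auto"` choice.
#' @param or_scale report the odds-ratio scale as well; defaults to the
#'   harmonized table's outcome type.
#' @return an [mr_estimate()] with method `ivw_fixed` or `ivw_random`;
#'   the heterogeneity triple is attached as `attr(x, "heterogeneity")`.
#' @export
mr_ivw <- function(table, effects = c("auto", "fixed", "random"),
                   q_alpha = 0.05, or_scale = .is_binary_outcome(table)) {
  effects <- match.arg(effects)
  tab <- .retained_tab(table, 1L, "IVW")
  r <- .ratio_stats(tab)
  k <- nrow(tab)
  if (all(r$x == 0)) stop("degenerate design: all exposure effects zero",
                          call. = FALSE)
  sxx <- sum(r$w_out * r$x^2)
  b <- sum(r$w_out * r$x * r$y) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(r$w_out * (r$y - b * r$x)^2)
  if (k == 1L) {
    est <- mr_estimate("ivw_fixed", 1L, b, se_fixed, or_scale = or_scale)
    attr(est, "heterogeneity") <- c(Q = 0, df = 0, p = 1)
    return(est)
  }
  q_p <- stats::pchisq(q, df = k - 1L, lower.tail = FALSE)
  if (effects == "auto") {
    effects <- if (q_p < q_alpha) "random" else "fixed"
  }
  se <- if (effects == "random") {
    se_fixed * sqrt(max(1, q / (k - 1)))
  } else {
    se_fixed
  }
  est <- mr_estimate(paste0("ivw_", effects), k, b, se, or_scale = or_scale)
  attr(est, "heterogeneity") <- c(Q = q, df = k - 1L, p = q_p)
  est
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the
#' exposure associations *with* an intercept (weights `1/se_out^2`).
#' Rows are first re-signed so every exposure association is
#' non-negative, the orientation under which the intercept — the average
#' directional pleiotropic effect — is meaningful.  The slope is the
#' causal estimate under the InSIDE assumption.  Standard errors use a
#' Student t reference with k-2 degrees of freedom and multiplicative
#' random-effects scaling `sqrt(max(1, Q_egger/(k-2)))`.
#'
#' @inheritParams mr_ivw
#' @return a list: `estimate` (the slope as an [mr_estimate()]),
#'   `intercept`, `intercept_se`, `intercept_p`, and the Egger
#'   heterogeneity statistic `q` with `df`.
#' @export
mr_egger <- function(table, or_scale = .is_binary_outcome(table)) {
  tab <- .retained_tab(table, 3L, "MR-Egger")
  k <- nrow(tab)
  s <- ifelse(tab$beta_exp < 0, -1, 1)
  x <- s * tab$beta_exp
  y <- s * tab$beta_out
  w <- 1 / tab$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  res <- y - cf[1L] - cf[2L] * x
  q <- sum(w * res^2)
  sigma2 <- q / (k - 2)
  # unscaled (residual-variance-1) coefficient SEs, then floored inflation
  xtx_inv <- chol2inv(chol(crossprod(sqrt(w) * cbind(1, x))))
  se_unscaled <- sqrt(diag(xtx_inv))
  infl <- sqrt(max(1, sigma2))
  se <- se_unscaled * infl
  # a numerically exact fit is degenerate: the data pin both
  # coefficients, so report zero SEs (p-values collapse to the floor)
  if (q < 1e-12 * max(1, sum(w * y^2))) se <- c(0, 0)
  est <- mr_estimate("egger", k, unname(cf[2L]), se[2L], df = k - 2,
                     or_scale = or_scale)
  int_p <- if (se[1L] == 0) {
    if (abs(cf[1L]) < 1e-8 * max(abs(y))) 1 else .Machine$double.xmin
  } else {
    2 * stats::pt(-abs(cf[1L] / se[1L]), df = k - 2)
  }
  list(estimate = est,
       intercept = unname(cf[1L]), intercept_se = unname(se[1L]),
       intercept_p = max(min(int_p, 1), .Machine$double.xmin),
       q = q, df = k - 2)
}

# weighted median of values b with weights w (linear interpolation in
# cumulative weight)
.weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1L] >= 0.5) return(b[1L])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  below <- max(which(s < 0.5))
  b[below] + (b[below + 1L] - b[below]) * (0.5 - s[below]) /
    (s[below + 1L] - s[below])
}

.boot_draws <- function(tab, n_boot) {
  k <- nrow(tab)
  list(bx = matrix(stats::rnorm(k * n_boot, tab$beta_exp, tab$se_exp), nrow = k),
       by = matrix(stats::rnorm(k * n_boot, tab$beta_out, tab$se_out), nrow = k))
}

#' Weighted-median estimate
#'
#' Orders the per-SNP Wald ratios and takes the value at which the
#' cumulative inverse-variance weight crosses 50%, interpolating
#' linearly between adjacent ratios.  Consistent when instruments
#' carrying at least half of the weight are valid.  Ratio variances use
#' the second-order delta method; the standard error comes from a
#' parametric bootstrap (associations resampled from their reported
#' SEs).
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed seed for the bootstrap.
#' @return an [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(table, n_boot = 1000, seed = 1,
                               or_scale = .is_binary_outcome(table)) {
  tab <- .retained_tab(table, 3L, "weighted median")
  r <- .ratio_stats(tab)
  est <- .weighted_median(r$ratio, 1 / r$se2^2)
  set.seed(seed)
  d <- .boot_draws(tab, n_boot)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- d$bx[, i]; by <- d$by[, i]
    bx[bx == 0] <- .Machine$double.eps
    ratio <- by / bx
    v <- tab$se_out^2 / bx^2 + by^2 * tab$se_exp^2 / bx^4
    .weighted_median(ratio, 1 / v)
  }, numeric(1L))
  se <- stats::sd(boots)
  mr_estimate("weighted_median", nrow(tab), est, se, or_scale = or_scale)
}

# exact weighted Gaussian-KDE argmax over a fine grid
.kde_mode <- function(ratio, w, h, grid_n = 512L) {
  if (h <= 0 || !is.finite(h)) return(ratio[1L])
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / h))
  grid[which.max(dens)]
}

.mode_bandwidth <- function(ratio, factor) {
  s <- stats::sd(ratio)
  m <- stats::mad(ratio)
  pool <- c(s, m[m > 0])
  factor * 0.9 * min(pool) * length(ratio)^(-1 / 5)
}

#' Mode-based estimate (simple and weighted)
#'
#' Smooths the empirical distribution of the per-SNP Wald ratios with a
#' Gaussian kernel and takes the density argmax — the estimate implied
#' by the largest cluster of agreeing instruments, consistent when the
#' most common ratio value comes from valid instruments (the ZEMPA
#' assumption).  The weighted variant weights each ratio by its inverse
#' variance.  The bandwidth is `bandwidth_factor` times a
#' modified-Silverman rule, `0.9 min(sd, mad) k^{-1/5}`, on the ratios.
#' When every ratio coincides the bandwidth degenerates and that common
#' value is returned.  Standard errors come from a parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param weighted inverse-variance weights (`TRUE`) or unit weights.
#' @param bandwidth_factor multiplier on the modified-Silverman
#'   bandwidth (default 1).
#' @param grid_n density-evaluation grid size.
#' @return an [mr_estimate()] with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(table, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1, grid_n = 512L,
                    or_scale = .is_binary_outcome(table)) {
  method <- if (weighted) "weighted_mode" else "simple_mode"
  tab <- .retained_tab(table, 3L, method)
  r <- .ratio_stats(tab)
  w <- if (weighted) 1 / r$se2^2 else rep(1, nrow(tab))
  w <- w / sum(w)
  h <- .mode_bandwidth(r$ratio, bandwidth_factor)
  est <- if (h <= 0 || !is.finite(h)) r$ratio[1L] else
    .kde_mode(r$ratio, w, h, grid_n)
  set.seed(seed)
  d <- .boot_draws(tab, n_boot)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- d$bx[, i]; by <- d$by[, i]
    bx[bx == 0] <- .Machine$double.eps
    ratio <- by / bx
    bw <- if (weighted) {
      v <- tab$se_out^2 / bx^2 + by^2 * tab$se_exp^2 / bx^4
      1 / v
    } else {
      rep(1, length(ratio))
    }
    bh <- .mode_bandwidth(ratio, bandwidth_factor)
    if (bh <= 0 || !is.finite(bh)) ratio[1L] else
      .kde_mode(ratio, bw / sum(bw), bh, grid_n)
  }, numeric(1L))
  se <- stats::sd(boots)
  mr_estimate(method, nrow(tab), est, se, or_scale = or_scale)
}

#' Run the full univariable estimator battery
#'
#' Computes the IVW estimate (fixed or random effects chosen by the
#' Cochran-Q heterogeneity test), MR-Egger, weighted median, simple
#' mode, and weighted mode on one harmonized table.  Methods whose
#' instrument-count floor is not met are recorded as not estimable
#' (`NA` estimate) rather than failing the batch.  Each method carries a
#' flag recording whether its effect direction agrees with IVW, the
#' consistency check usually reported alongside screening results.
#'
#' @inheritParams mr_weighted_median
#' @param q_alpha heterogeneity level for the IVW fixed/random choice.
#' @return a data.frame of class `mr_result`, one row per method, with
#'   columns `method`, `n_snp`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `direction_agrees_ivw`, `note` (and OR columns for binary
#'   outcomes).
#' @export
run_all_methods <- function(table, n_boot = 1000, seed = 1, q_alpha = 0.05,
                            or_scale = .is_binary_outcome(table)) {
  tab <- .retained_tab(table, 1L, "MR")
  k <- nrow(tab)
  rows <- list()
  notes <- character(0)

  add <- function(est, note = NA_character_) {
    rows[[length(rows) + 1L]] <<- est
    notes[length(notes) + 1L] <<- note
  }

  add(mr_ivw(tab, effects = "auto", q_alpha = q_alpha, or_scale = or_scale))
  if (k >= 3L) {
    add(mr_egger(tab, or_scale = or_scale)$estimate)
    add(mr_weighted_median(tab, n_boot = n_boot, seed = seed,
                           or_scale = or_scale))
    add(mr_mode(tab, weighted = FALSE, n_boot = n_boot, seed = seed + 1L,
                or_scale = or_scale))
    add(mr_mode(tab, weighted = TRUE, n_boot = n_boot, seed = seed + 2L,
                or_scale = or_scale))
  } else {
    for (m in c("egger", "weighted_median", "simple_mode", "weighted_mode")) {
      add(.not_estimable(m, k, or_scale), "not_estimable")
    }
  }
  out <- do.call(rbind, rows)
  out$note <- notes
  ivw_sign <- sign(out$beta[1L])
  out$direction_agrees_ivw <- ifelse(is.na(out$beta), NA,
                                     sign(out$beta) == ivw_sign)
  class(out) <- c("mr_result", "data.frame")
  attr(out, "exposure_name") <- attr(table, "exposure_name")
  attr(out, "outcome_name") <- attr(table, "outcome_name")
  out
}
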