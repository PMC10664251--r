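# Multivariable MR: joint instrument selection, random-effects IVW and
# Egger models over several exposures, and conditional instrument
# strength.

#' Construct a multivariable MR input
#'
#' Aligned summary-level data for a joint model: one row per instrument,
#' one column per exposure, plus the outcome associations.  All
#' associations must already be harmonized to a common effect allele.
#'
#' @param instruments character vector of SNP ids.
#' @param exposure_betas,exposure_ses numeric matrices, SNP x exposure.
#' @param outcome_beta,outcome_se numeric vectors, one per SNP.
#' @param exposure_names column labels for the exposures.
#' @return an object of class `mvmr_input`.
#' @export
mvmr_input <- function(instruments, exposure_betas, exposure_ses,
                       outcome_beta, outcome_se, exposure_names) {
  exposure_betas <- as.matrix(exposure_betas)
  exposure_ses <- as.matrix(exposure_ses)
  k <- length(instruments)
  m <- length(exposure_names)
  stopifnot(nrow(exposure_betas) == k, ncol(exposure_betas) == m,
            all(dim(exposure_ses) == dim(exposure_betas)),
            length(outcome_beta) == k, length(outcome_se) == k,
            all(outcome_se > 0), all(exposure_ses > 0))
  if (k < m + 1L) {
    stop("insufficient instruments: ", k, " for ", m,
         " exposures (need >= exposures + 1)", call. = FALSE)
  }
  colnames(exposure_betas) <- colnames(exposure_ses) <- exposure_names
  structure(list(instruments = as.character(instruments),
                 exposure_betas = exposure_betas,
                 exposure_ses = exposure_ses,
                 outcome_beta = as.numeric(outcome_beta),
                 outcome_se = as.numeric(outcome_se),
                 exposure_names = exposure_names),
            class = "mvmr_input")
}

#' @export
print.mvmr_input <- function(x, ...) {
  cat(sprintf("<mvmr_input> %d instrument(s) x %d exposure(s): %s\n",
              length(x$instruments), length(x$exposure_names),
              paste(x$exposure_names, collapse = ", ")))
  invisible(x)
}

# drop all-zero exposure columns (they carry no identifying information
# and make the design singular); report what was dropped
.mvmr_drop_null_columns <- function(input) {
  zero <- apply(input$exposure_betas, 2L, function(col) all(col == 0))
  if (any(zero)) {
    message("dropping exposure(s) with all-zero instrument effects: ",
            paste(input$exposure_names[zero], collapse = ", "))
    input <- mvmr_input(input$instruments,
                        input$exposure_betas[, !zero, drop = FALSE],
                        input$exposure_ses[, !zero, drop = FALSE],
                        input$outcome_beta, input$outcome_se,
                        input$exposure_names[!zero])
  }
  input
}

.mvmr_check_rank <- function(X, w, names) {
  qx <- qr(sqrt(w) * X)
  if (qx$rank < ncol(X)) {
    dropped <- names[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear exposure matrix; offending exposure(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
}

# weighted no-intercept multiple regression with multiplicative
# random-effects scaling floored at 1
.mvmr_wls <- function(X, y, w, df_resid, label, exposure_names,
                      t_dist = FALSE) {
  xtx <- crossprod(sqrt(w) * X)
  xtwy <- crossprod(X, w * y)
  xtx_inv <- chol2inv(chol(xtx))
  b <- drop(xtx_inv %*% xtwy)
  res <- y - drop(X %*% b)
  q <- sum(w * res^2)
  infl <- sqrt(max(1, q / df_resid))
  se <- sqrt(diag(xtx_inv)) * infl
  crit <- if (t_dist) stats::qt(0.975, df_resid) else stats::qnorm(0.975)
  p <- if (t_dist) 2 * stats::pt(-abs(b / se), df_resid) else
    2 * stats::pnorm(-abs(b / se))
  est <- data.frame(exposure = colnames(X), beta = b, se = se,
                    ci_low = b - crit * se, ci_high = b + crit * se,
                    pvalue = pmin(pmax(p, .Machine$double.xmin), 1),
                    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  list(estimates = est, Q = q, df = df_resid)
}

#' Multivariable IVW estimate
#'
#' Weighted multiple regression of the outcome associations on every
#' exposure's instrument associations, with no intercept and weights
#' `1/outcome_se^2`.  Each coefficient is the direct effect of that
#' exposure conditional on the others.  Standard errors carry
#' multiplicative random-effects scaling `sqrt(max(1, Q/(k - m)))`;
#' p-values are normal.  Exposures with all-zero instrument effects are
#' dropped (with a message) before fitting; any remaining rank
#' deficiency is an error naming the offending exposures.
#'
#' @param input an [mvmr_input()].
#' @return an object of class `mvmr_estimate`: a list with `estimates`
#'   (one row per exposure), `model`, `Q`, `df`.
#' @export
mvmr_ivw <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  input <- .mvmr_drop_null_columns(input)
  X <- input$exposure_betas
  y <- input$outcome_beta
  w <- 1 / input$outcome_se^2
  k <- nrow(X); m <- ncol(X)
  .mvmr_check_rank(X, w, input$exposure_names)
  fit <- .mvmr_wls(X, y, w, df_resid = k - m, label = "ivw_random",
                   exposure_names = input$exposure_names)
  structure(list(estimates = fit$estimates, model = "ivw_random",
                 Q = fit$Q, df = fit$df, n_snp = k),
            class = "mvmr_estimate")
}

#' Multivariable MR-Egger estimate
#'
#' As [mvmr_ivw()] but with an intercept term estimating the average
#' directional pleiotropic effect.  Rows are first re-signed so the
#' first exposure's instrument associations are non-negative (the
#' orientation that makes the intercept interpretable).  Inference uses
#' a Student t reference with k - m - 1 degrees of freedom.
#'
#' @param input an [mvmr_input()].
#' @return an `mvmr_estimate` whose `estimates` rows cover the exposures
#'   and whose `intercept`, `intercept_se`, `intercept_p` describe the
#'   pleiotropy term.
#' @export
mvmr_egger <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  input <- .mvmr_drop_null_columns(input)
  s <- ifelse(input$exposure_betas[, 1L] < 0, -1, 1)
  X <- input$exposure_betas * s
  y <- input$outcome_beta * s
  w <- 1 / input$outcome_se^2
  k <- nrow(X); m <- ncol(X)
  if (k < m + 2L) {
    stop("insufficient instruments for multivariable Egger: need >= ",
         m + 2L, call. = FALSE)
  }
  Xi <- cbind(`(intercept)` = 1, X)
  .mvmr_check_rank(Xi, w, c("(intercept)", input$exposure_names))
  fit <- .mvmr_wls(Xi, y, w, df_resid = k - m - 1L, label = "egger",
                   exposure_names = input$exposure_names, t_dist = TRUE)
  int <- fit$estimates[1L, ]
  structure(list(estimates = fit$estimates[-1L, ], model = "egger",
                 intercept = int$beta, intercept_se = int$se,
                 intercept_p = int$pvalue,
                 Q = fit$Q, df = fit$df, n_snp = k),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("<mvmr_estimate> model %s, %d instrument(s)\n",
              x$model, x$n_snp))
  print(x$estimates)
  if (!is.null(x$intercept)) {
    cat(sprintf("intercept %.4g (se %.4g, p %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Conditional instrument strength per exposure
#'
#' Measures how much independent instrument signal each exposure
#' retains once the other exposures' associations are accounted for.
#' For exposure i, its instrument associations are regressed (weights
#' `1/outcome_se^2`, no intercept) on all other exposures'
#' associations; the residuals are the conditionally unique part of the
#' signal, and the statistic is the residual mean chi-square
#' \deqn{F_i = \frac{\sum_j r_{ij}^2 / se_{ij}^2}{k - (m - 1)},}
#' an F-scale convention: with mutually orthogonal exposures it
#' approaches the mean per-SNP single-exposure F, and a perfectly
#' collinear (duplicated) exposure scores 0.  This is an approximation
#' to the conditional F of the econometric literature, not the exact
#' Sanderson-Windmeijer statistic; values above 10 are flagged
#' adequate, matching the usual weak-instrument rule.
#'
#' @param input an [mvmr_input()].
#' @return data.frame with columns `exposure`, `conditional_f`,
#'   `adequate` plus attribute `convention` describing the formula.
#' @export
conditional_f <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  X <- input$exposure_betas
  S <- input$exposure_ses
  w <- 1 / input$outcome_se^2
  k <- nrow(X); m <- ncol(X)
  stopifnot(m >= 2L)
  f <- vapply(seq_len(m), function(i) {
    others <- X[, -i, drop = FALSE]
    sw <- sqrt(w)
    qx <- qr(sw * others)
    r <- if (qx$rank == 0L) X[, i] else {
      fitted <- qr.fitted(qx, sw * X[, i]) / sw
      X[, i] - fitted
    }
    sum(r^2 / S[, i]^2) / (k - (m - 1L))
  }, numeric(1L))
  out <- data.frame(exposure = input$exposure_names, conditional_f = f,
                    adequate = f > 10, stringsAsFactors = FALSE)
  attr(out, "convention") <-
    "residual mean chi-square after weighted projection on co-exposures (approximate conditional F)"
  out
}

#' Joint instrument selection for multivariable MR
#'
#' Builds the instrument panel for a joint model: each exposure is
#' screened at `pval`, the survivors are pooled, the pooled panel is
#' LD-clumped greedily using each SNP's smallest p-value across
#' exposures as its clumping p, and the clumped SNPs are then required
#' to be present in every exposure set and in the outcome.  All
#' associations are aligned to the first exposure's effect alleles via
#' [harmonize()] (palindromic ambiguity handled with its default
#' policy).
#'
#' @param exposures list of [summary_stats()] objects (>= 2); the first
#'   is the primary exposure whose allele orientation is used.
#' @param outcome a [summary_stats()] object.
#' @param ld an [ld_reference()].
#' @param pval per-exposure significance threshold (default 5e-6).
#' @param r2_max,window_kb clumping parameters.
#' @return an [mvmr_input()].
#' @export
mvmr_select_instruments <- function(exposures, outcome, ld, pval = 5e-6,
                                    r2_max = 0.001, window_kb = 10000) {
  stopifnot(length(exposures) >= 2L)
  sig <- lapply(exposures, filter_by_pvalue, threshold = pval)
  pool_ids <- unique(unlist(lapply(sig, function(s) s$snp_id)))
  if (length(pool_ids) == 0L) {
    stop("no SNP passes the significance screen in any exposure",
         call. = FALSE)
  }
  # pooled records, clumping p = min across exposures
  min_p <- rep(Inf, length(pool_ids))
  names(min_p) <- pool_ids
  for (s in sig) {
    idx <- match(s$snp_id, pool_ids)
    min_p[idx] <- pmin(min_p[idx], s$pvalue)
  }
  first <- as.data.frame(exposures[[1L]])
  src <- do.call(rbind, lapply(sig, as.data.frame))
  src <- src[!duplicated(src$snp_id), , drop = FALSE]
  src <- src[src$snp_id %in% pool_ids, , drop = FALSE]
  src$pvalue <- min_p[src$snp_id]
  pooled <- summary_stats(src, trait_name = "mvmr_pool")
  clumped <- ld_clump(pooled, ld, r2_max = r2_max, window_kb = window_kb)

  keep <- clumped$snp_id
  for (s in exposures) keep <- intersect(keep, s$snp_id)
  keep <- intersect(keep, outcome$snp_id)
  exposure_names <- vapply(exposures, attr, character(1L), "trait_name")

  ref <- exposures[[1L]]
  ref_sub <- .ss_update(ref, as.data.frame(ref)[ref$snp_id %in% keep, ,
                                                drop = FALSE], "mvmr_keep")
  align_to_ref <- function(set) {
    h <- retained(harmonize(ref_sub, set))
    stats::setNames(h$beta_out, h$snp_id)
  }
  align_se <- function(set) {
    h <- retained(harmonize(ref_sub, set))
    stats::setNames(h$se_out, h$snp_id)
  }
  beta_cols <- c(list(stats::setNames(ref_sub$beta, ref_sub$snp_id)),
                 lapply(exposures[-1L], align_to_ref),
                 list(align_to_ref(outcome)))
  se_cols <- c(list(stats::setNames(ref_sub$se, ref_sub$snp_id)),
               lapply(exposures[-1L], align_se),
               list(align_se(outcome)))
  ids <- Reduce(intersect, lapply(beta_cols, names))
  m <- length(exposures)
  if (length(ids) < m + 1L) {
    stop("insufficient instruments after joint selection: ", length(ids),
         " for ", m, " exposures", call. = FALSE)
  }
  ids <- sort(ids)
  mvmr_input(
    instruments = ids,
    exposure_betas = vapply(beta_cols[seq_len(m)], function(v) v[ids],
                            numeric(length(ids))),
    exposure_ses = vapply(se_cols[seq_len(m)], function(v) v[ids],
                          numeric(length(ids))),
    outcome_beta = beta_cols[[m + 1L]][ids],
    outcome_se = se_cols[[m + 1L]][ids],
    exposure_names = exposure_names)
}
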