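test_that("Wald ratio arithmetic and delta-method standard errors", {
  est <- wald_ratio(0.2, 0.05, 0.1, 0.02)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(0.2, 0.05, 0, 0.02)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "beta_exp")

  so <- wald_ratio(0.2, 0.05, 0.1, 0.02, second_order = TRUE)
  expect_equal(so$se, sqrt(0.02^2 / 0.2^2 + 0.1^2 * 0.05^2 / 0.2^4),
               tolerance = 1e-12)
})

test_that("IVW equals the weighted-least-squares oracle and handles degeneracy", {
  # single SNP reduces to the Wald ratio
  tab1 <- make_tab(0.2, 0.05, 0.1, 0.02)
  est1 <- mr_ivw(tab1)
  expect_equal(est1$beta, 0.5)
  expect_equal(est1$se, 0.1)
  expect_identical(est1$method, "ivw_fixed")

  # identical ratios: zero heterogeneity, fixed = random
  tab2 <- make_tab(c(0.1, 0.2, 0.4), rep(0.01, 3),
                   c(0.05, 0.10, 0.20), c(0.01, 0.02, 0.01))
  f <- mr_ivw(tab2, effects = "fixed")
  r <- mr_ivw(tab2, effects = "random")
  expect_equal(f$beta, 0.5, tolerance = 1e-12)
  expect_equal(attr(f, "heterogeneity")[["Q"]], 0, tolerance = 1e-20)
  expect_equal(f$se, r$se)

  # 3-SNP worked table against the normal-equations oracle
  tab3 <- make_tab(c(0.1, 0.2, 0.3), rep(0.01, 3),
                   c(0.05, 0.11, 0.14), c(0.01, 0.01, 0.02))
  w <- 1 / tab3$se_out^2
  b_oracle <- wls_oracle(matrix(tab3$beta_exp), tab3$beta_out, w)
  est3 <- mr_ivw(tab3, effects = "fixed")
  expect_equal(est3$beta, b_oracle, tolerance = 1e-10)
  # fixed-effects estimate is also sum(w r)/sum(w) with ratio weights
  wr <- tab3$beta_exp^2 / tab3$se_out^2
  expect_equal(est3$beta,
               sum(wr * tab3$beta_out / tab3$beta_exp) / sum(wr),
               tolerance = 1e-10)
})

test_that("IVW agrees with metafor's fixed-effects meta-analysis of ratios", {
  skip_if_not_installed("metafor")
  tab <- make_noisy_tab(k = 8, theta = 0.4, seed = 2)
  ratio <- tab$beta_out / tab$beta_exp
  se1 <- tab$se_out / abs(tab$beta_exp)
  fit <- metafor::rma(yi = ratio, sei = se1, method = "FE")
  est <- mr_ivw(tab, effects = "fixed")
  expect_equal(est$beta, as.numeric(fit$beta), tolerance = 1e-8)
  expect_equal(est$se, fit$se, tolerance = 1e-8)
})

test_that("Egger regression recovers exact lines and matches the WLS oracle", {
  x <- c(0.1, 0.15, 0.2, 0.3)
  # through the origin: slope theta, intercept 0
  tab <- make_tab(x, rep(0.01, 4), 0.4 * x, rep(0.01, 4))
  e <- mr_egger(tab)
  expect_equal(e$estimate$beta, 0.4, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-10)

  # constant offset: slope theta, intercept alpha, degenerate-perfect fit
  tab2 <- make_tab(x, rep(0.01, 4), 0.05 + 0.4 * x, rep(0.01, 4))
  e2 <- mr_egger(tab2)
  expect_equal(e2$estimate$beta, 0.4, tolerance = 1e-10)
  expect_equal(e2$intercept, 0.05, tolerance = 1e-10)
  expect_lt(e2$intercept_p, 1e-200)

  # noisy 10-SNP table against the normal-equations oracle
  tab3 <- make_noisy_tab(k = 10, theta = 0.4, intercept = 0.02, seed = 1)
  w <- 1 / tab3$se_out^2
  cf <- wls_oracle(cbind(1, tab3$beta_exp), tab3$beta_out, w)
  e3 <- mr_egger(tab3)
  expect_equal(e3$intercept, cf[1], tolerance = 1e-10)
  expect_equal(e3$estimate$beta, cf[2], tolerance = 1e-10)

  expect_error(mr_egger(make_tab(0.1, 0.01, 0.05, 0.01)), "insufficient")
})

test_that("weighted median interpolates cumulative weight at 50%", {
  # symmetric equal-weight ratios
  tab <- make_tab(c(1, 1, 1), rep(1e-8, 3), c(0.4, 0.5, 0.6), rep(0.01, 3))
  est <- mr_weighted_median(tab, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)

  # identical ratios: that value, small positive bootstrap SE
  tab2 <- make_tab(c(0.1, 0.2, 0.4), rep(0.001, 3),
                   c(0.05, 0.10, 0.20), rep(0.001, 3))
  est2 <- mr_weighted_median(tab2, n_boot = 200, seed = 2)
  expect_equal(est2$beta, 0.5, tolerance = 1e-10)
  expect_gt(est2$se, 0)
  expect_lt(est2$se, 0.05)

  # majority-valid robustness: 10 valid + 3 wildly invalid instruments
  set.seed(7)
  x <- runif(13, 0.1, 0.3)
  y <- 0.4 * x
  y[11:13] <- y[11:13] + 0.15   # pleiotropic minority
  tab3 <- make_tab(x, rep(0.005, 13), y + rnorm(13, 0, 0.004),
                   rep(0.005, 13))
  est3 <- mr_weighted_median(tab3, n_boot = 500, seed = 7)
  expect_gt(est3$ci_high, 0.4)
  expect_lt(est3$ci_low, 0.4)
  # and the invalid minority drags IVW off the truth
  expect_gt(mr_ivw(tab3, effects = "fixed")$beta, est3$beta)
})

test_that("mode estimators find the dominant ratio cluster", {
  tab <- make_tab(c(0.1, 0.2, 0.4), rep(0.001, 3),
                  c(0.05, 0.10, 0.20), rep(0.001, 3))
  est <- mr_mode(tab, weighted = FALSE, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 1e-6)

  # 7 ratios near 0.5 plus 3 outliers at 2.0
  set.seed(3)
  x <- rep(0.2, 10)
  y <- c(0.5 * x[1:7] + rnorm(7, 0, 0.002), 2.0 * x[8:10])
  sy <- c(rep(0.004, 7), rep(0.05, 10 - 7))
  tab2 <- make_tab(x, rep(0.002, 10), y, sy)
  simple <- mr_mode(tab2, weighted = FALSE, n_boot = 200, seed = 3)
  expect_lt(abs(simple$beta - 0.5), 0.1)
  # KDE-argmax oracle on a dense grid (independent reimplementation)
  ratio <- tab2$beta_out / tab2$beta_exp
  h <- 0.9 * min(sd(ratio), mad(ratio)) * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 4096)
  dens <- sapply(grid, function(g) sum(dnorm((g - ratio) / h)))
  expect_equal(simple$beta, grid[which.max(dens)], tolerance = 0.005)

  # inverse-variance weighting pins the mode on the precise valid
  # instruments: outliers and noisy ratios get tiny weights, so the
  # weighted estimate is nearer the truth with a much tighter bootstrap
  # spread than the unweighted one
  set.seed(3)
  x3 <- rep(0.2, 13)
  y3 <- c(0.5 * x3[1:3] + rnorm(3, 0, 0.0005),     # ultra-precise valid
          0.5 * x3[4:10] + rnorm(7, 0, 0.02),      # noisy valid
          2.0 * x3[11:13] + rnorm(3, 0, 0.05))     # smeared outliers
  sy3 <- c(rep(0.001, 3), rep(0.03, 7), rep(0.08, 3))
  tab3 <- make_tab(x3, rep(0.001, 13), y3, sy3)
  simple3 <- mr_mode(tab3, weighted = FALSE, n_boot = 300, seed = 3)
  weighted3 <- mr_mode(tab3, weighted = TRUE, n_boot = 300, seed = 3)
  expect_lt(abs(weighted3$beta - 0.5), abs(simple3$beta - 0.5))
  expect_lt(weighted3$se, simple3$se / 2)
})

test_that("run_all_methods batches the five estimators with direction flags", {
  # one instrument: only IVW(=Wald) is estimable
  res1 <- run_all_methods(make_tab(0.2, 0.05, 0.1, 0.02), n_boot = 50)
  expect_equal(sum(is.na(res1$beta)), 4L)
  expect_identical(res1$note[res1$method == "egger"], "not_estimable")
  expect_equal(res1$beta[res1$method == "ivw_fixed"], 0.5)

  # noise-free proportional table: every method agrees on theta
  x <- c(0.1, 0.15, 0.2, 0.3)
  res2 <- run_all_methods(make_tab(x, rep(0.01, 4), 0.3 * x, rep(0.01, 4)),
                          n_boot = 50, seed = 1)
  expect_true(all(abs(res2$beta - 0.3) < 1e-6))
  expect_true(all(res2$direction_agrees_ivw))

  # binary outcomes gain an exponentiated scale
  tabb <- make_tab(x, rep(0.01, 4), 0.3 * x, rep(0.01, 4),
                   outcome_type = "binary")
  resb <- run_all_methods(tabb, n_boot = 50, seed = 1)
  expect_true(all(c("or", "or_ci_low", "or_ci_high") %in% names(resb)))
  expect_equal(resb$or, exp(resb$beta))
  expect_equal(resb$or_ci_low, exp(resb$ci_low))
})

test_that("estimates are scale- and orientation-equivariant", {
  tab <- make_noisy_tab(k = 8, theta = 0.4, seed = 5)
  base <- run_all_methods(tab, n_boot = 100, seed = 9)

  # outcome rescaling multiplies every estimate by the same constant
  sc <- tab
  sc$beta_out <- 3 * sc$beta_out
  sc$se_out <- 3 * sc$se_out
  scaled <- run_all_methods(sc, n_boot = 100, seed = 9)
  expect_equal(scaled$beta, 3 * base$beta, tolerance = 1e-6)

  # flipping the exposure's effect allele (and re-harmonizing, which
  # flips the outcome too) leaves every estimate unchanged
  fl <- tab
  fl$beta_exp <- -fl$beta_exp
  fl$beta_out <- -fl$beta_out
  flipped <- run_all_methods(fl, n_boot = 100, seed = 9)
  expect_equal(flipped$beta, base$beta, tolerance = 1e-10)
})
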