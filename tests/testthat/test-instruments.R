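test_that("p-value and MAF filters apply the stated thresholds and commute", {
  rec <- make_records(3, seed = 1)
  rec$pvalue <- c(1e-8, 1e-5, 0.2)
  set <- summary_stats(rec)
  expect_equal(nrow(filter_by_pvalue(set, 5e-6)), 1L)
  expect_equal(nrow(filter_by_pvalue(set, 5e-8)), 1L)
  expect_equal(nrow(filter_by_pvalue(set, 1 - 1e-12)), 3L)

  rec <- make_records(3, seed = 2)
  rec$eaf <- c(0.005, 0.995, 0.5)
  set <- summary_stats(rec)
  kept <- filter_by_maf(set, 0.01)
  expect_identical(kept$snp_id, "rs3")

  # commutation + audit conservation on a random set
  rec <- make_records(50, seed = 3)
  rec$eaf[7] <- 0.002
  set <- summary_stats(rec)
  a <- filter_by_maf(filter_by_pvalue(set, 0.3), 0.01)
  b <- filter_by_pvalue(filter_by_maf(set, 0.01), 0.3)
  expect_identical(a$snp_id, b$snp_id)
  audit <- attr(a, "audit")
  expect_equal(sum(audit$removed) + nrow(a), nrow(set))
})

toy_ld <- function(ids, chrom, pos, pairs = NULL) {
  p <- if (is.null(pairs)) {
    data.frame(snp_id_a = character(0), snp_id_b = character(0), r2 = numeric(0))
  } else {
    pairs
  }
  ld_reference(p, data.frame(snp_id = ids, chrom = chrom, pos = pos))
}

test_that("greedy clumping follows p-order, window and r2 rules", {
  # different chromosomes never clump, even with no LD records
  rec <- make_records(2, seed = 4)
  rec$chrom <- c("1", "2"); rec$pos <- c(1e6, 1e6)
  set <- summary_stats(rec)
  ld <- toy_ld(rec$snp_id, rec$chrom, rec$pos)
  expect_equal(nrow(ld_clump(set, ld)), 2L)

  # 5 kb apart, r2 = 0.9: only the stronger SNP survives
  rec$chrom <- c("1", "1"); rec$pos <- c(1e6, 1e6 + 5e3)
  rec$pvalue <- c(1e-9, 1e-7)
  set <- summary_stats(rec)
  ld <- toy_ld(rec$snp_id, rec$chrom, rec$pos,
               data.frame(snp_id_a = "rs1", snp_id_b = "rs2", r2 = 0.9))
  out <- ld_clump(set, ld, r2_max = 0.001, window_kb = 10000)
  expect_identical(out$snp_id, "rs1")

  # chain A-B 0.5, B-C 0.5, A-C 0: greedy keeps {A, C}
  rec <- make_records(3, seed = 5)
  rec$chrom <- "1"; rec$pos <- c(1e6, 1.01e6, 1.02e6)
  rec$pvalue <- c(1e-9, 1e-8, 1e-7)
  set <- summary_stats(rec)
  ld <- toy_ld(rec$snp_id, rec$chrom, rec$pos,
               data.frame(snp_id_a = c("rs1", "rs2"),
                          snp_id_b = c("rs2", "rs3"),
                          r2 = c(0.5, 0.5)))
  out <- ld_clump(set, ld, r2_max = 0.1, window_kb = 10000)
  expect_setequal(out$snp_id, c("rs1", "rs3"))

  # missing position map entry is a hard error naming the SNP
  ld_bad <- toy_ld("rs1", "1", 1e6)
  expect_error(ld_clump(set, ld_bad, 0.1, 10000), "rs2")
})

test_that("clumping output is pairwise independent; degenerate limits hold", {
  set.seed(6)
  pair <- generate_pair(test_config(), truth_record(), seed = 6)
  sig <- filter_by_pvalue(pair$exposure, 0.05)
  out <- ld_clump(sig, pair$ld, r2_max = 0.001, window_kb = 10000)
  lk <- mrbiome:::.ld_lookup(pair$ld, out$snp_id)
  pos <- pair$ld$positions
  idx <- match(out$snp_id, pos$snp_id)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i >= j) next
      if (pos$chrom[idx[i]] != pos$chrom[idx[j]]) next
      if (abs(pos$pos[idx[i]] - pos$pos[idx[j]]) > 1e7) next
      expect_lt(lk(out$snp_id[i], out$snp_id[j]), 0.001)
    }
  }
  # r2_max = 1 never clumps distinct SNPs
  expect_equal(nrow(ld_clump(sig, pair$ld, r2_max = 1, window_kb = 10000)),
               nrow(sig))
  # window 0 only clumps exact-position duplicates
  expect_equal(nrow(ld_clump(sig, pair$ld, r2_max = 0.001, window_kb = 0)),
               nrow(sig))
})

test_that("variance explained matches the printed formula and its algebra", {
  expect_equal(variance_explained(0.3, 0, 0.01, 1000), 0)
  # hand evaluation: beta^2/(beta^2 + n se^2) with the frequency factor
  # cancelling
  expect_equal(variance_explained(0.5, 0.1, 0.01, 10000),
               0.01 / (0.01 + 1), tolerance = 1e-12)
  r2 <- variance_explained(seq(0.05, 0.95, by = 0.1), 0.1, 0.01, 10000)
  expect_true(all(abs(r2 - r2[1]) < 1e-14))
  expect_error(variance_explained(0, 0.1, 0.01, 1000), "eaf")
})

test_that("F statistic follows r2 (n-2)/(1-r2) and composes with R2", {
  expect_equal(f_statistic(0, 5000), 0)
  expect_equal(f_statistic(0.009901, 10000),
               0.009901 * 9998 / (1 - 0.009901), tolerance = 1e-12)
  # identity: F(R2(eaf, beta, se, n), n) = (n-2) beta^2 / (n se^2)
  set.seed(7)
  for (i in 1:20) {
    eaf <- runif(1, 0.05, 0.95); beta <- rnorm(1, 0, 0.1)
    se <- runif(1, 0.005, 0.05); n <- sample(5000:50000, 1)
    expect_equal(f_statistic(variance_explained(eaf, beta, se, n), n),
                 (n - 2) * beta^2 / (n * se^2), tolerance = 1e-10)
  }
})

test_that("two-stage selection relaxes the threshold and removes weak instruments", {
  set.seed(8)
  pair <- generate_pair(generator_config(n_snps = 200, ld_block_size = 5,
                                         n_instruments = 5,
                                         instrument_z_range = c(4.6, 5.0)),
                        truth_record(), seed = 8)
  inst <- select_instruments(pair$exposure, pair$ld)
  # taxa-style data rarely clear 5e-8; the relaxed stage must engage
  audit <- attr(inst, "audit")
  expect_true(any(grepl("pvalue<5e-06", audit$step)))
  expect_true(all(inst$f_stat > 10))
  expect_true(all(inst$pvalue < 5e-6))

  # a strongly-powered exposure keeps the strict stage
  pair2 <- generate_pair(test_config(instrument_z_range = c(12, 20)),
                         truth_record(), seed = 9)
  inst2 <- select_instruments(pair2$exposure, pair2$ld)
  expect_true(any(grepl("pvalue<5e-08", attr(inst2, "audit")$step)))
})

test_that("Steiger filtering compares per-side variance explained", {
  # r2_exp > r2_out: TRUE and retained; reverse: FALSE and removed
  tab <- make_tab(beta_exp = c(0.1, 0.01, 0.1), se_exp = rep(0.01, 3),
                  beta_out = c(0.01, 0.1, 0.02), se_out = rep(0.012, 3))
  st <- steiger_filter(tab)
  expect_identical(st$verdicts$verdict, c(TRUE, FALSE, TRUE))
  expect_identical(retained(st$table)$snp_id, c("rs1", "rs3"))
  expect_identical(st$table$reason[2], "steiger_false")

  # forward-causal synthetic data: no removals expected
  pair <- generate_pair(test_config(), truth_record(true_theta = 0.4),
                        seed = 10)
  tab <- harmonize(select_instruments(pair$exposure, pair$ld), pair$outcome)
  st <- steiger_filter(tab)
  expect_equal(sum(!st$verdicts$verdict), 0L)

  # rows lacking outcome eaf pass with a warning, marked untestable
  tab2 <- make_tab(0.1, 0.01, 0.01, 0.012)
  tab2$eaf_out <- NA_real_
  expect_warning(st2 <- steiger_filter(tab2), "untestable")
  expect_true(st2$verdicts$untestable)
  expect_true(st2$verdicts$verdict)
})
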