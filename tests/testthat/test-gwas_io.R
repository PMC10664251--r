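test_that("summary statistics survive a write/read round trip", {
  # 3-line toy file with standard headers
  rec <- make_records(3, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  set <- summary_stats(rec, trait_name = "toy")
  write_summary_stats(set, path)
  back <- read_summary_stats(path, trait_name = "toy")
  expect_equal(nrow(back), 3L)

  # 100 random records, fixed seed, sorted canonical order both ways
  rec <- make_records(100, seed = 7)
  set <- summary_stats(rec, trait_name = "big")
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_summary_stats(set, gz)
  back <- read_summary_stats(gz, trait_name = "big")
  o1 <- order(set$snp_id); o2 <- order(back$snp_id)
  for (col in c("snp_id", "chrom", "effect_allele", "other_allele")) {
    expect_identical(set[[col]][o1], back[[col]][o2])
  }
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    expect_equal(set[[col]][o1], back[[col]][o2], tolerance = 1e-12)
  }
})

test_that("reader normalizes alleles and reports malformed input", {
  rec <- make_records(2, seed = 2)
  rec$effect_allele <- c("a", "g")
  rec$other_allele <- c("g", "a")
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  set <- read_summary_stats(path)
  expect_identical(set$effect_allele, c("A", "G"))

  # non-numeric beta names the file line (header is line 1)
  rec2 <- make_records(3, seed = 3)
  rec2$beta <- as.character(rec2$beta)
  rec2$beta[2] <- "oops"
  write.table(rec2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "line\\(s\\) 3")

  # missing required column is a configuration error
  write.table(rec2[, -3], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "configuration error")
})

test_that("writer rejects empty sets and writes one line per record", {
  set <- summary_stats(make_records(1, seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(set, path)
  expect_length(readLines(path), 2L)

  empty <- summary_stats(make_records(1)[0, ])
  expect_error(write_summary_stats(empty, path), "empty")
  write_summary_stats(empty, path, allow_empty = TRUE)
  expect_length(readLines(path), 1L)
})

test_that("summary_stats validates its invariants", {
  rec <- make_records(3, seed = 5)
  rec$snp_id[2] <- rec$snp_id[1]
  expect_error(summary_stats(rec), "duplicated")
  rec <- make_records(3, seed = 5)
  rec$other_allele[1] <- rec$effect_allele[1]
  expect_error(summary_stats(rec), "allele")
  rec <- make_records(3, seed = 5)
  rec$se[1] <- 0
  expect_error(summary_stats(rec), "se")
})

make_pair_sets <- function() {
  e <- make_records(4, seed = 10)
  e$effect_allele <- c("A", "A", "A", "C")
  e$other_allele <- c("G", "G", "T", "G")
  e$eaf <- c(0.3, 0.3, 0.2, 0.4)
  e$beta <- c(0.1, 0.1, 0.1, 0.1)
  o <- e
  # rs1 matched; rs2 swapped alleles; rs3 palindromic; rs4 mismatched
  o$effect_allele <- c("A", "G", "A", "C")
  o$other_allele <- c("G", "A", "T", "A")
  o$beta <- c(0.05, 0.05, 0.02, 0.01)
  o$eaf <- c(0.3, 0.3, 0.2, 0.4)
  list(exposure = summary_stats(e, trait_name = "exp"),
       outcome = summary_stats(o, trait_name = "out", trait_role = "outcome"))
}

test_that("harmonization aligns, flips, and drops as specified", {
  s <- make_pair_sets()
  tab <- harmonize(s$exposure, s$outcome)

  r1 <- tab[tab$snp_id == "rs1", ]
  expect_false(r1$dropped)
  expect_equal(r1$beta_out, 0.05)

  r2 <- tab[tab$snp_id == "rs2", ]
  expect_false(r2$dropped)
  expect_equal(r2$beta_out, -0.05)
  expect_equal(r2$eaf_out, 0.7)

  # palindromic at orientable frequency: kept, frequencies agree
  r3 <- tab[tab$snp_id == "rs3", ]
  expect_false(r3$dropped)
  expect_true(r3$palindromic)

  r4 <- tab[tab$snp_id == "rs4", ]
  expect_true(r4$dropped)
  expect_identical(r4$reason, "allele_mismatch")
})

test_that("ambiguous palindromic SNPs are dropped under the default policy", {
  e <- make_records(1, seed = 11)
  e$effect_allele <- "A"; e$other_allele <- "T"; e$eaf <- 0.5
  o <- e
  tab <- harmonize(summary_stats(e), summary_stats(o, trait_role = "outcome"))
  expect_true(tab$dropped)
  expect_identical(tab$reason, "palindromic_ambiguous")

  tab_all <- harmonize(summary_stats(e), summary_stats(o, trait_role = "outcome"),
                       palindrome_policy = "drop_all")
  expect_identical(tab_all$reason, "palindromic")
  tab_keep <- harmonize(summary_stats(e), summary_stats(o, trait_role = "outcome"),
                        palindrome_policy = "keep")
  expect_false(tab_keep$dropped)
})

test_that("harmonization bookkeeping: conservation, idempotence, involution", {
  set.seed(20)
  cfg <- test_config()
  pair <- generate_pair(cfg, truth_record(true_theta = 0.3), seed = 20)
  tab <- harmonize(pair$exposure, pair$outcome)

  # retained + dropped = shared SNP count
  shared <- sum(pair$exposure$snp_id %in% pair$outcome$snp_id)
  expect_equal(sum(!tab$dropped) + sum(tab$dropped & tab$reason != "not_in_outcome"),
               shared)

  # idempotence: re-harmonizing the harmonized outcome changes nothing
  kept <- retained(tab)
  out2 <- summary_stats(data.frame(
    snp_id = kept$snp_id, chrom = kept$chrom, pos = kept$pos,
    effect_allele = kept$effect_allele, other_allele = kept$other_allele,
    eaf = kept$eaf_out, beta = kept$beta_out, se = kept$se_out,
    pvalue = 2 * pnorm(-abs(kept$beta_out / kept$se_out)), n = kept$n_out),
    trait_role = "outcome")
  tab2 <- harmonize(pair$exposure, out2)
  kept2 <- retained(tab2)
  expect_equal(kept2$beta_out, kept$beta_out)
  expect_equal(kept2$eaf_out, kept$eaf_out)

  # involution: swapping the outcome alleles and negating its betas
  # yields the same retained table
  o <- as.data.frame(pair$outcome)
  swapped <- o
  swapped$effect_allele <- o$other_allele
  swapped$other_allele <- o$effect_allele
  swapped$beta <- -o$beta
  swapped$eaf <- 1 - o$eaf
  tab3 <- harmonize(pair$exposure,
                    summary_stats(swapped, trait_role = "outcome"))
  kept3 <- retained(tab3)
  expect_identical(kept3$snp_id, kept$snp_id)
  expect_equal(kept3$beta_out, kept$beta_out)

  # empty intersection warns and returns an empty table
  lone_rec <- make_records(1, seed = 30)
  lone_rec$snp_id <- "rs99999"
  lone <- summary_stats(lone_rec)
  expect_warning(tab0 <- harmonize(lone, pair$outcome), "no SNPs shared")
  expect_equal(sum(!tab0$dropped), 0L)
})
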