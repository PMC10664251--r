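# Synthetic GWAS summary-statistic generator with known ground truth:
# paired exposure/outcome panels, block-structured LD references, and a
# hierarchical taxa panel, so every pipeline stage is testable without
# downloading cohort data.

#' Generator configuration
#'
#' Parameters of the synthetic GWAS model.  Defaults emulate the data
#' structure of a nicotine-dependence / gut-microbiota screen: an
#' exposure cohort of 38,602, an outcome (microbiota) cohort of 18,340,
#' and a 211-taxon panel split 9/16/20/35/131 across
#' phylum/class/order/family/genus.  Per-SNP standard errors follow the
#' allele-frequency algebra `se = 1/sqrt(2 maf (1-maf) n)`, which makes
#' the summary-level variance-explained identity hold by construction.
#'
#' Two regimes are supported for the true SNP-exposure effects: a
#' polygenic regime (`n_instruments = NULL`), where every SNP draws
#' `gamma ~ Normal(0, exposure_effect_sd^2)`, and a planted regime,
#' where `n_instruments` SNPs in distinct LD blocks receive effects of
#' `instrument_z_range` standard errors so the selected instruments'
#' F-statistics land in the tens — the band where the F > 10 screen is
#' a real constraint rather than a formality.
#'
#' @param n_snps SNPs in the panel.
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes (>= 1000
#'   so standard errors stay on a realistic scale).
#' @param maf_range range of simulated minor-allele frequencies.
#' @param exposure_effect_sd SD of polygenic true effects.
#' @param ld_block_size SNPs per LD block.
#' @param within_block_r2 r-squared between SNPs of the same block
#'   (between blocks it is 0).
#' @param n_instruments planted strong instruments (or `NULL` for the
#'   polygenic regime).
#' @param instrument_z_range range of |true effect| / SE for planted
#'   instruments.
#' @param ensure_significant redraw a planted instrument's observed
#'   effect until it passes `sig_threshold`, guaranteeing the planted
#'   count survives selection (used by the taxa panel, where the
#'   per-taxon instrument count is a design quantity).
#' @param sig_threshold threshold used by `ensure_significant`.
#' @param taxa_counts named integer vector of taxa per level.
#' @param instrument_range inclusive range that per-taxon planted
#'   instrument counts are drawn from (default 3-13).
#' @param binary_outcome treat the outcome trait as binary (effects are
#'   log odds ratios; downstream estimates gain an OR scale).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_snps = 1000,
                             n_exposure_sample = 38602,
                             n_outcome_sample = 18340,
                             maf_range = c(0.05, 0.5),
                             exposure_effect_sd = 0.015,
                             ld_block_size = 10,
                             within_block_r2 = 0.8,
                             n_instruments = NULL,
                             instrument_z_range = c(6, 10),
                             ensure_significant = FALSE,
                             sig_threshold = 5e-6,
                             taxa_counts = c(phylum = 9, class = 16,
                                             order = 20, family = 35,
                                             genus = 131),
                             instrument_range = c(3, 13),
                             binary_outcome = FALSE) {
  stopifnot(n_snps >= 1, ld_block_size >= 1,
            n_exposure_sample >= 1000, n_outcome_sample >= 1000,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            within_block_r2 >= 0, within_block_r2 <= 1,
            all(names(taxa_counts) %in% .TAXON_LEVELS),
            instrument_range[1] >= 1,
            instrument_range[2] >= instrument_range[1])
  if (!is.null(n_instruments)) {
    stopifnot(n_instruments >= 1,
              n_instruments <= ceiling(n_snps / ld_block_size))
  }
  structure(list(n_snps = n_snps,
                 n_exposure_sample = n_exposure_sample,
                 n_outcome_sample = n_outcome_sample,
                 maf_range = maf_range,
                 exposure_effect_sd = exposure_effect_sd,
                 ld_block_size = ld_block_size,
                 within_block_r2 = within_block_r2,
                 n_instruments = n_instruments,
                 instrument_z_range = instrument_z_range,
                 ensure_significant = ensure_significant,
                 sig_threshold = sig_threshold,
                 taxa_counts = taxa_counts,
                 instrument_range = instrument_range,
                 binary_outcome = binary_outcome),
            class = "generator_config")
}

#' Ground-truth record for a synthetic dataset
#'
#' Everything needed to predict how the estimators should behave on a
#' generated dataset: the true causal effect, the pleiotropy model
#' (`none`, `balanced` — zero-mean direct effects, or `directional` —
#' mean-shifted direct effects, the violation MR-Egger targets), any
#' planted outliers, a reverse-direction effect for directionality
#' tests, and the seeds used.
#'
#' @param true_theta causal effect of exposure on outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"`.
#' @param pleiotropy_sd,pleiotropy_mean parameters of the per-SNP direct
#'   effects.
#' @param reverse_theta when non-zero, the data are generated with the
#'   *outcome* as the genetically proximal trait and this effect back
#'   onto the exposure (so Steiger verdicts should fail).
#' @param outlier_snps planted outlier SNP ids (filled by
#'   [plant_outliers()]).
#' @param seeds seeds used during generation.
#' @return a list of class `truth_record`.
#' @export
truth_record <- function(true_theta = 0,
                         pleiotropy_mode = c("none", "balanced",
                                             "directional"),
                         pleiotropy_sd = 0, pleiotropy_mean = 0,
                         reverse_theta = 0, outlier_snps = character(),
                         seeds = integer()) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  structure(list(true_theta = true_theta,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 reverse_theta = reverse_theta,
                 outlier_snps = outlier_snps,
                 seeds = seeds),
            class = "truth_record")
}

# shared SNP panel scaffolding: positions, blocks, frequencies, alleles
.make_panel <- function(config) {
  n <- config$n_snps
  bs <- config$ld_block_size
  block <- ceiling(seq_len(n) / bs)
  n_block <- max(block)
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  idx_within <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  pos <- 1e6 + idx_within * 5e4
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  ea <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  # non-palindromic other allele: neither the effect allele nor its
  # complement, so harmonization is never frequency-ambiguous
  oa <- vapply(ea, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), c(a, .COMPLEMENT[[a]])), 1L)
  }, character(1L))
  pairs <- NULL
  if (config$within_block_r2 > 0 && bs > 1L) {
    plist <- lapply(seq_len(n_block), function(b) {
      ids <- which(block == b)
      if (length(ids) < 2L) return(NULL)
      cmb <- utils::combn(ids, 2L)
      data.frame(a = cmb[1L, ], b = cmb[2L, ])
    })
    pairs <- do.call(rbind, plist)
  }
  list(n = n, block = block, n_block = n_block, chrom = chrom, pos = pos,
       maf = maf, ea = ea, oa = oa,
       snp_id = paste0("rs", seq_len(n)), pairs = pairs)
}

.panel_ld <- function(panel, config) {
  pairs <- if (is.null(panel$pairs)) {
    data.frame(snp_id_a = character(0), snp_id_b = character(0),
               r2 = numeric(0))
  } else {
    data.frame(snp_id_a = panel$snp_id[panel$pairs$a],
               snp_id_b = panel$snp_id[panel$pairs$b],
               r2 = config$within_block_r2, stringsAsFactors = FALSE)
  }
  ld_reference(pairs,
               data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                          pos = panel$pos, stringsAsFactors = FALSE))
}

# true effects for one trait on the panel: polygenic or planted
.true_effects <- function(panel, config, k_planted = config$n_instruments) {
  se <- 1 / sqrt(2 * panel$maf * (1 - panel$maf) * config$n_exposure_sample)
  if (is.null(k_planted)) {
    gamma <- stats::rnorm(panel$n, 0, config$exposure_effect_sd)
    list(gamma = gamma, planted = integer(0))
  } else {
    gamma <- numeric(panel$n)
    blocks <- sample(panel$n_block, k_planted)
    at <- vapply(blocks, function(b) {
      ids <- which(panel$block == b)
      ids[sample.int(length(ids), 1L)]
    }, integer(1L))
    z <- stats::runif(k_planted, config$instrument_z_range[1],
                      config$instrument_z_range[2])
    gamma[at] <- sample(c(-1, 1), k_planted, replace = TRUE) * z * se[at]
    list(gamma = gamma, planted = at)
  }
}

.observe <- function(true_beta, se, planted = integer(0),
                     ensure = FALSE, threshold = 5e-6) {
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  if (ensure && length(planted) > 0L) {
    for (i in planted) {
      tries <- 0L
      while (2 * stats::pnorm(-abs(beta[i] / se[i])) >= threshold &&
             tries < 50L) {
        beta[i] <- stats::rnorm(1L, true_beta[i], se[i])
        tries <- tries + 1L
      }
    }
  }
  beta
}

.as_sumstats <- function(panel, beta, se, n, trait_name, trait_role,
                         taxon_level = "none", trait_type = "continuous") {
  summary_stats(data.frame(
    snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
    effect_allele = panel$ea, other_allele = panel$oa,
    eaf = panel$maf, beta = beta, se = se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)), n = n,
    stringsAsFactors = FALSE),
    trait_name = trait_name, trait_role = trait_role,
    taxon_level = taxon_level, trait_type = trait_type)
}

#' Generate one paired exposure/outcome dataset
#'
#' Simulates a two-sample design on a shared SNP panel.  True
#' SNP-exposure effects `gamma_j` come from the configured regime;
#' per-SNP direct (pleiotropic) effects `alpha_j` follow the truth
#' record's pleiotropy mode; true SNP-outcome effects are
#' `theta * gamma_j + alpha_j`.  Observed effects add independent
#' normal noise with the allele-frequency-derived standard errors of
#' each cohort, and p-values are two-sided Wald tests.  When
#' `truth$reverse_theta` is non-zero the construction is mirrored: the
#' outcome is the genetically proximal trait and the exposure inherits
#' `reverse_theta` times its effects — the configuration Steiger
#' filtering is meant to catch.
#'
#' @param config a [generator_config()].
#' @param truth a [truth_record()].
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param exposure_name,outcome_name trait labels.
#' @return list with elements `exposure`, `outcome` (two
#'   [summary_stats()]), `ld` (an [ld_reference()]), and `truth` (the
#'   input record with the seed appended).
#' @export
generate_pair <- function(config, truth = truth_record(), seed = 1,
                          exposure_name = "exposure",
                          outcome_name = "outcome") {
  stopifnot(inherits(config, "generator_config"),
            inherits(truth, "truth_record"))
  set.seed(seed)
  panel <- .make_panel(config)
  se_exp <- 1 / sqrt(2 * panel$maf * (1 - panel$maf) *
                       config$n_exposure_sample)
  se_out <- 1 / sqrt(2 * panel$maf * (1 - panel$maf) *
                       config$n_outcome_sample)
  alpha <- switch(truth$pleiotropy_mode,
                  none = numeric(panel$n),
                  balanced = stats::rnorm(panel$n, 0, truth$pleiotropy_sd),
                  directional = stats::rnorm(panel$n, truth$pleiotropy_mean,
                                             truth$pleiotropy_sd))
  eff <- .true_effects(panel, config)
  if (truth$reverse_theta != 0) {
    # outcome-proximal construction: genetics -> outcome -> exposure.
    # The exposure-side effects keep the configured instrument scale (so
    # selection still works) and the outcome effects are their source,
    # larger by 1/reverse_theta
    true_exp <- eff$gamma
    true_out <- eff$gamma / truth$reverse_theta + alpha
  } else {
    true_exp <- eff$gamma
    true_out <- truth$true_theta * eff$gamma + alpha
  }
  beta_exp <- .observe(true_exp, se_exp, eff$planted,
                       config$ensure_significant, config$sig_threshold)
  beta_out <- stats::rnorm(panel$n, true_out, se_out)
  truth$seeds <- c(truth$seeds, seed)
  truth$planted_snps <- panel$snp_id[eff$planted]
  truth$true_gamma <- eff$gamma
  list(exposure = .as_sumstats(panel, beta_exp, se_exp,
                               config$n_exposure_sample, exposure_name,
                               "exposure"),
       outcome = .as_sumstats(panel, beta_out, se_out,
                              config$n_outcome_sample, outcome_name,
                              "outcome",
                              trait_type = if (config$binary_outcome)
                                "binary" else "continuous"),
       ld = .panel_ld(panel, config),
       truth = truth)
}

#' Generate a hierarchical taxa panel with known ground truth
#'
#' Builds a full microbiota-style screening panel on one shared SNP
#' panel: a manifest of taxa split across the five taxonomic levels per
#' `config$taxa_counts` (default 9 phyla, 16 classes, 20 orders, 35
#' families, 131 genera — 211 taxa), one summary-statistics set per
#' taxon with a planted instrument count drawn uniformly from
#' `config$instrument_range` (default 3-13, enforced through
#' significance-conditioned draws so the design count survives
#' selection), and a single trait set whose associations sum the causal
#' taxa's contributions.  Most taxa are null; `n_causal` of them (chosen
#' at random) carry effect `causal_theta` on the trait.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @param n_causal number of causal taxa.
#' @param causal_theta effect of each causal taxon on the trait.
#' @return list with `manifest` (a [taxa_manifest()]), `taxa` (named
#'   list of per-taxon [summary_stats()], role exposure), `trait` (the
#'   trait outcome set), `ld`, and `truths` (named list of
#'   [truth_record()]s).
#' @export
generate_taxa_panel <- function(config = generator_config(), seed = 1,
                                n_causal = 0, causal_theta = 0.3) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  counts <- config$taxa_counts
  taxon <- unlist(lapply(names(counts), function(lv) {
    sprintf("%s_%03d", lv, seq_len(counts[[lv]]))
  }))
  level <- rep(names(counts), counts)
  manifest <- taxa_manifest(taxon, level)
  n_taxa <- nrow(manifest)
  stopifnot(n_causal <= n_taxa)
  causal <- sample(n_taxa, n_causal)

  panel <- .make_panel(config)
  # taxa GWAS are the smaller (outcome-size) cohort; the trait GWAS the
  # larger one
  se_taxa <- 1 / sqrt(2 * panel$maf * (1 - panel$maf) *
                        config$n_outcome_sample)
  se_trait <- 1 / sqrt(2 * panel$maf * (1 - panel$maf) *
                         config$n_exposure_sample)

  taxa_cfg <- config
  taxa_cfg$n_exposure_sample <- config$n_outcome_sample

  taxa <- vector("list", n_taxa)
  truths <- vector("list", n_taxa)
  names(taxa) <- names(truths) <- manifest$taxon
  trait_true <- numeric(panel$n)
  for (t in seq_len(n_taxa)) {
    k_t <- sample(seq(config$instrument_range[1],
                      config$instrument_range[2]), 1L)
    eff <- .true_effects(panel, taxa_cfg, k_planted = k_t)
    beta_t <- .observe(eff$gamma, se_taxa, eff$planted,
                       ensure = TRUE, threshold = config$sig_threshold)
    theta_t <- if (t %in% causal) causal_theta else 0
    trait_true <- trait_true + theta_t * eff$gamma
    taxa[[t]] <- .as_sumstats(panel, beta_t, se_taxa,
                              config$n_outcome_sample, manifest$taxon[t],
                              "exposure", taxon_level = manifest$level[t])
    truths[[t]] <- truth_record(true_theta = theta_t, seeds = seed)
    truths[[t]]$planted_snps <- panel$snp_id[eff$planted]
    truths[[t]]$n_planted <- k_t
  }
  beta_trait <- stats::rnorm(panel$n, trait_true, se_trait)
  trait <- .as_sumstats(panel, beta_trait, se_trait,
                        config$n_exposure_sample, "trait", "outcome",
                        trait_type = if (config$binary_outcome) "binary"
                        else "continuous")
  list(manifest = manifest, taxa = taxa, trait = trait,
       ld = .panel_ld(panel, config), truths = truths)
}

#' Plant pleiotropic outliers in a generated pair
#'
#' Adds `offset_scale` outcome standard errors to the outcome
#' association of `k_outliers` randomly chosen candidate instruments
#' (SNPs passing `candidate_p` in the exposure), recording them in the
#' truth record.  Used to exercise MR-PRESSO detection.
#'
#' @param pair a list from [generate_pair()].
#' @param k_outliers number of outliers; must be fewer than half of the
#'   candidate instruments.
#' @param offset_scale offset in units of the SNP's outcome SE.
#' @param seed RNG seed for the choice of SNPs.
#' @param candidate_p exposure significance defining the candidate pool.
#' @return the modified pair with `truth$outlier_snps` filled.
#' @export
plant_outliers <- function(pair, k_outliers, offset_scale = 10, seed = 1,
                           candidate_p = 5e-6) {
  stopifnot(k_outliers >= 0)
  if (k_outliers == 0L) return(pair)
  candidates <- which(pair$exposure$pvalue < candidate_p)
  if (k_outliers >= length(candidates) / 2) {
    stop("k_outliers must be below half the candidate instrument count (",
         length(candidates), ")", call. = FALSE)
  }
  set.seed(seed)
  chosen <- sample(candidates, k_outliers)
  out <- as.data.frame(pair$outcome)
  out$beta[chosen] <- out$beta[chosen] + offset_scale * out$se[chosen]
  out$pvalue[chosen] <- 2 * stats::pnorm(-abs(out$beta[chosen] /
                                                out$se[chosen]))
  pair$outcome <- .ss_update(pair$outcome, out, "plant_outliers")
  pair$truth$outlier_snps <- c(pair$truth$outlier_snps,
                               pair$exposure$snp_id[chosen])
  pair
}
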