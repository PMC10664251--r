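---
title: "Methods: bidirectional two-sample MR between a behavioural trait and the gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR between a behavioural trait and the gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbiome)
```

## The problem

Observational studies report associations between nicotine dependence and
the composition of the gut microbiota, but confounding (diet, comorbidity,
other smoking behaviours) and reverse causation make those associations
hard to interpret. Two-sample Mendelian randomization (MR) sidesteps both
by using germline genetic variants as instrumental variables: a variant
that robustly shifts the exposure, is independent of confounders, and
affects the outcome only through the exposure identifies the causal effect
of the exposure on the outcome from GWAS summary statistics alone.

`mrbiome` implements that design for a many-taxa screen: one behavioural
trait (nicotine dependence, measured on the Fagerström scale in a cohort
of 38,602 ex-smokers) against a microbiota GWAS panel of 211 taxa spread
over five taxonomic levels (9 phyla, 16 classes, 20 orders, 35 families,
131 genera; 18,340 participants), run in both causal directions, with a
multivariable extension that adjusts the trait for four smoking-related
phenotypes. Because the cohort-level data sit behind access controls, the
package pairs the analysis code with a synthetic summary-statistic
generator with known ground truth, so every stage is testable end to end.

## Instrument selection

For each exposure we apply, in order:

* **Significance.** Genome-wide significance ($p < 5\times10^{-8}$) first;
  if fewer than 3 SNPs survive clumping — the norm for microbial taxa —
  the screen relaxes to $p < 5\times10^{-6}$. Strict inequality is used;
  the boundary case is immaterial at these magnitudes.
* **Frequency.** Minor-allele frequency $\ge 0.01$.
* **Independence.** Greedy LD clumping at $r^2 < 0.001$ within
  10,000 kb: the most significant unclaimed SNP becomes an index SNP and
  claims all correlated neighbours; ties in $p$ break by genomic
  coordinate so results are deterministic. Pairs absent from the LD
  reference count as independent, and the reference is a plain table of
  $(a, b, r^2)$ records so any panel — including a synthetic one — can
  stand in for a population reference.
* **Strength.** Per-SNP variance explained
  $R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
  {2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2+2\,\mathrm{EAF}(1-\mathrm{EAF})N\,\mathrm{SE}^2}$
  (the frequency factor cancels; we evaluate the full expression and test
  the cancellation as an invariant) and $F = R^2(N-2)/(1-R^2)$;
  instruments with $F \le 10$ are removed as weak.
* **Direction.** Steiger filtering: a SNP whose variance explained in the
  outcome exceeds that in the exposure is evidence the SNP is
  outcome-proximal; such SNPs are excluded. The default is the plain
  $R^2$ comparison (a TRUE/FALSE verdict); a z-test variant that only
  fails significantly reversed SNPs is available but off by default.

## Harmonization

Outcome associations are aligned to the exposure's effect allele: swapped
alleles flip the sign and complement the frequency; strand flips are
resolved by complement matching. Palindromic SNPs (A/T, C/G) cannot be
strand-resolved from alleles alone, so by default they are oriented by
allele frequency when the minor-allele frequency is below 0.42 in both
studies and dropped as ambiguous otherwise; `drop_all` and `keep`
policies are provided. Every dropped row carries a machine-readable
reason, and retained + dropped always accounts for every shared SNP.

## Estimators

All five standard summary-data estimators operate on the per-SNP Wald
ratios $\hat\theta_j = \hat\beta_{out,j}/\hat\beta_{exp,j}$:

* **IVW** — weighted regression of outcome on exposure associations
  through the origin, weights $1/\mathrm{se}_{out}^2$; equivalently the
  inverse-variance meta-analysis of the Wald ratios. Fixed effects force
  residual variance 1; the multiplicative random-effects model inflates
  the SE by $\sqrt{\max(1, Q/(k-1))}$ and is chosen automatically when
  Cochran's Q rejects at 0.05, mirroring screening practice.
* **MR-Egger** — the same regression with an intercept, fitted after
  re-signing rows to non-negative exposure effects. The slope is the
  causal estimate under InSIDE; the intercept estimates average
  directional pleiotropy and is reported with a $t_{k-2}$ test. A
  numerically exact fit pins both coefficients, so SEs collapse to zero
  and p-values to the floating-point floor rather than to misleading
  finite values.
* **Weighted median** — the ratio value at which cumulative
  inverse-variance weight (second-order delta-method variances) crosses
  50%, linearly interpolated; consistent while valid instruments carry a
  weight majority. SE by parametric bootstrap (default 1000 resamples,
  seeded).
* **Simple and weighted mode** — the argmax of a Gaussian-kernel density
  over the ratios, bandwidth `bandwidth_factor` (default 1) times the
  modified-Silverman rule $0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$,
  evaluated exactly on a 512-point grid spanning the ratios ±3 bandwidths.
  The weighted variant weights ratios by inverse variance; the simple
  variant is the same machinery with unit weights. If every ratio
  coincides the bandwidth degenerates and that common value is returned.

A one-instrument table degenerates to the Wald ratio (first-order SE by
default, second-order behind a flag). `run_all_methods()` runs the
battery, records methods below their instrument floor as `not_estimable`
instead of failing, and flags per-method direction agreement with IVW —
the consistency statement screening reports usually make. Binary
outcomes (log odds-ratio associations) additionally get an exponentiated
OR scale.

## Sensitivity suite

Cochran's Q (IVW and Egger parameterizations), the Egger intercept test,
leave-one-out IVW (with removals flagged when they change the sign or
leave the full-table confidence interval — the fixed-effects interval,
since a gross outlier would otherwise inflate the random-effects interval
enough to mask its own influence), funnel-plot data (ratio vs precision),
and MR-PRESSO. Our MR-PRESSO implementation follows the published
three-part scheme: a global test comparing the observed leave-one-out
weighted residual sum of squares against a parametric null (outcome
associations redrawn from the no-pleiotropy fit, default 1000 draws), a
per-SNP outlier test Bonferroni-corrected across instruments at 0.05,
and, when outliers are found, an outlier-corrected IVW plus a
permutation-style distortion test against random same-size removals.
Exceedance p-values are floored at $1/n_{sim}$ and flagged, never
reported as zero. Rows are processed in canonical SNP order, so the
result is invariant to input row order and bit-reproducible under a
fixed seed. When the screen finds outliers, the corrected estimates
replace the headline row and the uncorrected run is kept in the
sensitivity bundle.

## Multivariable MR

For the smoking-phenotype adjustment the package fits one joint model
(the default; pairwise adjustment is just repeated calls with two
exposures): instruments are screened per exposure at $5\times10^{-6}$,
pooled, jointly clumped using each SNP's best p-value, required in every
exposure and the outcome, and aligned to the first exposure's alleles.
`mvmr_ivw()` is the weighted no-intercept multiple regression with
random-effects scaling $\sqrt{\max(1, Q/(k-m))}$; `mvmr_egger()` adds an
intercept after orienting on the first exposure. Instrument strength per
exposure uses a conditional statistic: the exposure's instrument effects
are projected (outcome-precision weighted) on the other exposures'
effects and the residual mean chi-square
$F_i = \sum_j r_{ij}^2/\mathrm{se}_{ij}^2 \,/\, (k-m+1)$ is reported,
with $F > 10$ flagged adequate. This is deliberately an approximation:
the exact Sanderson–Windmeijer conditional F needs covariance inputs
that two-sample summary data do not provide, and the output labels the
convention. It behaves as required at the boundaries — it approaches the
univariable mean chi-square for orthogonal exposures and collapses to
zero for duplicated ones.

## Multiplicity and classification

Each taxonomic level is its own family of tests: the threshold is
$0.05/n$ with $n$ the number of taxa *analyzed* at that level in the
run at hand (so data loss changes the denominator, as it should), e.g.
$3.125\times10^{-3}$ for 16 classes and $3.906\times10^{-4}$ for 128
genera. P-values below the level threshold are `significant`, between
the threshold and 0.05 `potentially_significant`, otherwise
`not_significant`; pairs that yield no usable instruments are
`not_estimable` with a reason, and the per-level counts always add back
to the manifest.

## The synthetic generator

`generate_pair()` simulates the two-sample design directly at the
summary level: minor-allele frequencies uniform on a configurable range
(default 0.05–0.5), per-SNP standard errors
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,N}$ — which makes the
variance-explained algebra above hold exactly by construction — true
SNP-exposure effects $\gamma_j$, direct effects $\alpha_j$ (none,
balanced, or directional), true outcome effects
$\theta\gamma_j+\alpha_j$, and independent observation noise per cohort.
Default sample sizes are 38,602 (trait) and 18,340 (taxa), the sizes of
the GWAS the package is aimed at. LD is block-structured: blocks of 10
SNPs at within-block $r^2 = 0.8$, zero between blocks — enough to make
clumping non-trivial while keeping the reference small. Alleles are
drawn non-palindromic so harmonization never silently discards synthetic
instruments; palindromic handling is exercised by dedicated fixtures
instead. A reverse mode makes the outcome the genetically proximal trait
(exposure effects are `reverse_theta` times outcome effects), which is
what Steiger filtering must catch.

Two effect regimes matter:

* **Planted regime (default for testing):** `n_instruments` SNPs in
  distinct blocks get effects of 6–10 standard errors. The resulting
  F-statistics land in the tens — the band reported for real
  nicotine-dependence and taxa instruments (roughly F 17–88) — so the
  $F>10$ filter, the two-stage threshold, and type-I calibration are
  exercised under realistic instrument strength.
* **Strong regime (recovery checks):** effects of 15–30 standard errors.
  Parameter recovery is an asymptotic consistency property; at the
  realistic F band Egger, the weighted median and the modes carry the
  well-documented finite-sample weak-instrument attenuation of order
  $1/z^2$ (a property of the estimators, not of an implementation), so
  consistency is asserted where the estimators are consistent, and the
  realistic band is used for everything else.

`generate_taxa_panel()` builds the full 211-taxon structure on one SNP
panel, drawing each taxon's instrument count uniformly from 3–13 (the
range reported for real taxa) and conditioning the planted draws on
passing the selection threshold so the design count is what the screen
sees; most taxa are null and a configurable few are causal.
`plant_outliers()` adds a fixed number of outcome-side offsets (default
10 SEs) to exercise MR-PRESSO.

What the generator does *not* emulate: correlation between the observed
effects of SNPs in LD (LD affects only the clumping bookkeeping),
sample overlap between cohorts, taxonomically correlated taxa
abundances, count-compositional microbiome noise, and population
stratification. Passing tests therefore demonstrate the statistical
machinery under its stated assumptions, not robustness to those
real-data complications.

## Numerical conventions and edge cases

* P-values are clamped to $[\,\texttt{.Machine\$double.xmin}, 1]$; no
  statistic ever reports exactly zero.
* Wald ratios require $\hat\beta_{exp}\neq 0$; an all-zero exposure
  design is a hard error for IVW, and each estimator reports a clear
  `insufficient instruments` error below its floor (2 for Q, 3 for
  Egger/median/modes, 4 for MR-PRESSO).
* An all-zero exposure column in MVMR is dropped with a message (the
  model then reduces exactly to the remaining exposures); genuine
  collinearity is an error naming the offending exposures.
* Clumping ties break by chromosome, position, SNP id; all exported
  randomness is seed-controlled, and batch runs derive per-pair seeds
  from the configured base seed, so whole screens are byte-reproducible.

## Problem sizes used in the test and acceptance suites

Simulation suites use 200-SNP panels (blocks of 5, 12 planted
instruments), 200 replicates for recovery means, 1000 replicates for
type-I calibration, and 100 replicates at 1000 null simulations each for
MR-PRESSO power and size — sizes chosen so the whole suite documents the
statistical claims while remaining comfortable to run on a laptop.

## Known limitations

Proxy-SNP lookup, COJO-style conditional selection, radial MR, the
Rucker framework, I²GX diagnostics, MVMR-median/PRESSO and other
estimators outside the five implemented here are deliberately out of
scope. The conditional F is an approximation (above). Real-data effect
estimates for specific taxa require the access-controlled cohort data
and are outside what this package can reproduce; what it reproduces is
the analytic scaffolding — thresholds, bookkeeping, estimator algebra,
and the statistical behaviour of the full pipeline on data with known
truth.
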