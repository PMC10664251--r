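# Data model and I/O for GWAS summary statistics, LD references, and
# exposure-outcome harmonization.

.SS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pvalue", "n")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complement <- function(a) unname(.COMPLEMENT[a])

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Construct a summary-statistics set
#'
#' A `mr_sumstats` object holds one trait's per-SNP GWAS associations
#' (effect sizes on the effect-allele scale, standard errors, allele
#' frequencies, p-values and sample sizes) together with trait metadata.
#' It is the unit that all instrument-selection and harmonization
#' functions operate on; one set corresponds, for example, to one
#' bacterial taxon of a microbiota GWAS panel.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   Alleles are upper-cased on construction; `eaf` may be `NA`.
#' @param trait_name label of the trait.
#' @param trait_role one of `"exposure"`, `"outcome"`, `"covariate"`.
#' @param taxon_level taxonomic level for microbiota traits
#'   (`"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`) or
#'   `"none"` for non-taxon traits.
#' @param trait_type `"continuous"` or `"binary"`; binary traits are
#'   assumed to carry log odds-ratio effect sizes and trigger OR-scale
#'   reporting downstream.
#' @return an object of class `mr_sumstats` (a data.frame with trait
#'   metadata and a selection-audit table as attributes).
#' @export
summary_stats <- function(records, trait_name = "trait",
                          trait_role = c("exposure", "outcome", "covariate"),
                          taxon_level = c("none", "phylum", "class", "order",
                                          "family", "genus"),
                          trait_type = c("continuous", "binary")) {
  trait_role <- match.arg(trait_role)
  taxon_level <- match.arg(taxon_level)
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SS_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, .SS_COLS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (anyDuplicated(records$snp_id)) {
    stop("duplicated snp_id in summary statistics for '", trait_name, "'",
         call. = FALSE)
  }
  bad_allele <- !(records$effect_allele %in% names(.COMPLEMENT)) |
    !(records$other_allele %in% names(.COMPLEMENT)) |
    records$effect_allele == records$other_allele
  if (any(bad_allele)) {
    stop("invalid allele pair for SNP(s): ",
         paste(utils::head(records$snp_id[bad_allele], 5L), collapse = ", "),
         call. = FALSE)
  }
  ok <- is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)
  if (!all(ok)) stop("eaf outside [0, 1]", call. = FALSE)
  if (any(records$se <= 0, na.rm = TRUE)) stop("se must be > 0", call. = FALSE)
  if (any(records$pos < 1, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)
  rownames(records) <- NULL
  structure(records,
            class = c("mr_sumstats", "data.frame"),
            trait_name = trait_name, trait_role = trait_role,
            taxon_level = taxon_level, trait_type = trait_type,
            audit = data.frame(step = "input", removed = 0L,
                               retained = nrow(records),
                               stringsAsFactors = FALSE))
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("<mr_sumstats> trait '%s' (%s%s, %s): %d SNP(s)\n",
              attr(x, "trait_name"), attr(x, "trait_role"),
              if (attr(x, "taxon_level") != "none")
                paste0(", ", attr(x, "taxon_level")) else "",
              attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

# Keep metadata through subsetting, append one audit row.
.ss_update <- function(set, records, step) {
  audit <- attr(set, "audit")
  audit <- rbind(audit, data.frame(step = step,
                                   removed = nrow(set) - nrow(records),
                                   retained = nrow(records),
                                   stringsAsFactors = FALSE))
  rownames(records) <- NULL
  structure(as.data.frame(records),
            class = c("mr_sumstats", "data.frame"),
            trait_name = attr(set, "trait_name"),
            trait_role = attr(set, "trait_role"),
            taxon_level = attr(set, "taxon_level"),
            trait_type = attr(set, "trait_type"),
            audit = audit)
}

.open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated table with a header row.  A column-name mapping
#' (`dialect`) lets files with foreign headers (different consortia name
#' the same quantities differently) be read without rewriting them: it is
#' a named character vector `c(internal_name = "file_column")`.
#'
#' @param path file path; `.gz` files are decompressed transparently.
#' @param dialect optional named character vector mapping the internal
#'   schema (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`) to the file's column names.
#' @inheritParams summary_stats
#' @return a [summary_stats()] object.
#' @export
read_summary_stats <- function(path, dialect = NULL, trait_name = NULL,
                               trait_role = "exposure", taxon_level = "none",
                               trait_type = "continuous") {
  con <- .open_read(path)
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    missing_map <- setdiff(unname(dialect), names(raw))
    if (length(missing_map) > 0L) {
      stop("configuration error: mapped column(s) absent from file: ",
           paste(missing_map, collapse = ", "), call. = FALSE)
    }
    for (internal in names(dialect)) {
      names(raw)[names(raw) == dialect[[internal]]] <- internal
    }
  }
  missing_cols <- setdiff(.SS_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("configuration error: required column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("beta", "se")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0L) {
      # +1 for the header line so numbers match the file as seen in an editor
      stop("parse error: non-numeric ", col, " at line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    }
  }
  summary_stats(raw,
                trait_name = if (is.null(trait_name))
                  sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
                else trait_name,
                trait_role = trait_role, taxon_level = taxon_level,
                trait_type = trait_type)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Rows are sorted by chromosome, position and SNP id so output is
#' deterministic and the write/read round trip is lossless.
#'
#' @param set a [summary_stats()] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param allow_empty write a header-only file instead of erroring on an
#'   empty set.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(set, path, allow_empty = FALSE) {
  stopifnot(inherits(set, "mr_sumstats"))
  if (nrow(set) == 0L && !allow_empty) {
    stop("refusing to write an empty summary-statistics set ",
         "(use allow_empty = TRUE for a header-only file)", call. = FALSE)
  }
  df <- as.data.frame(set)[, .SS_COLS]
  o <- order(.chrom_rank(df$chrom), df$pos, df$snp_id)
  df <- df[o, , drop = FALSE]
  con <- .open_write(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# numeric chromosomes sort numerically, X/Y/MT after
.chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), 100 + match(chrom, sort(unique(chrom[is.na(num)]))), num)
}

#' Construct an LD reference
#'
#' Pairwise r-squared records plus a per-SNP position map, the minimal
#' linkage-disequilibrium information needed for clumping.  Pairs are
#' stored symmetrically; a pair absent from the table is taken to have
#' r-squared zero, and a SNP with itself has r-squared one.
#'
#' @param pairs data.frame with columns `snp_id_a`, `snp_id_b`, `r2`.
#' @param positions data.frame with columns `snp_id`, `chrom`, `pos`.
#' @return an object of class `mr_ld`.
#' @export
ld_reference <- function(pairs, positions) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  positions <- as.data.frame(positions, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id_a", "snp_id_b", "r2") %in% names(pairs)),
            all(c("snp_id", "chrom", "pos") %in% names(positions)))
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    stop("r2 outside [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(positions$snp_id)) {
    stop("duplicated snp_id in LD position map", call. = FALSE)
  }
  structure(list(pairs = pairs, positions = positions), class = "mr_ld")
}

#' @export
print.mr_ld <- function(x, ...) {
  cat(sprintf("<mr_ld> %d pair record(s), %d mapped SNP(s)\n",
              nrow(x$pairs), nrow(x$positions)))
  invisible(x)
}

#' Read / write an LD reference
#'
#' Both tables are tab-separated with headers; `.gz` paths are handled
#' transparently.
#'
#' @param pairs_path path of the pairwise r-squared table
#'   (`snp_id_a`, `snp_id_b`, `r2`).
#' @param positions_path path of the per-SNP position map
#'   (`snp_id`, `chrom`, `pos`).
#' @return [read_ld_reference()] returns an [ld_reference()] object;
#'   [write_ld_reference()] returns its paths invisibly.
#' @export
read_ld_reference <- function(pairs_path, positions_path) {
  con <- .open_read(pairs_path)
  pairs <- utils::read.delim(con, stringsAsFactors = FALSE)
  close(con)
  con <- .open_read(positions_path)
  positions <- utils::read.delim(con, stringsAsFactors = FALSE)
  close(con)
  positions$snp_id <- as.character(positions$snp_id)
  positions$chrom <- as.character(positions$chrom)
  pairs$snp_id_a <- as.character(pairs$snp_id_a)
  pairs$snp_id_b <- as.character(pairs$snp_id_b)
  ld_reference(pairs, positions)
}

#' @param ld an [ld_reference()] object.
#' @rdname read_ld_reference
#' @export
write_ld_reference <- function(ld, pairs_path, positions_path) {
  stopifnot(inherits(ld, "mr_ld"))
  con <- .open_write(pairs_path)
  utils::write.table(ld$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  con <- .open_write(positions_path)
  utils::write.table(ld$positions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(c(pairs_path, positions_path))
}

.harmonized_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                      "beta_exp", "se_exp", "eaf_exp", "n_exp", "pvalue_exp",
                      "beta_out", "se_out", "eaf_out", "n_out",
                      "palindromic", "dropped", "reason")

.new_harmonized <- function(df, exposure, outcome) {
  rownames(df) <- NULL
  structure(df, class = c("mr_harmonized", "data.frame"),
            exposure_name = attr(exposure, "trait_name"),
            outcome_name = attr(outcome, "trait_name"),
            outcome_type = attr(outcome, "trait_type"))
}

#' Retained rows of a harmonized table
#'
#' @param table an `mr_harmonized` table from [harmonize()].
#' @return the subset of rows whose `dropped` flag is `FALSE`.
#' @export
retained <- function(table) {
  stopifnot(inherits(table, "mr_harmonized"))
  table[!table$dropped, , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations of every SNP shared between the two
#' studies to the exposure's effect allele.  If the outcome's alleles are
#' swapped relative to the exposure, the outcome effect changes sign and
#' its allele frequency is complemented; strand flips (A<->T, C<->G on
#' both alleles) are resolved by complement matching.  Pairs that match
#' neither directly, swapped, nor after a strand flip are dropped with
#' reason `"allele_mismatch"`.  Palindromic SNPs (A/T or C/G pairs), for
#' which strand cannot be resolved from the alleles alone, are handled by
#' `palindrome_policy`:
#'
#' * `"drop_ambiguous"` (default): orient by allele frequency when both
#'   studies have a frequency far enough from 0.5 (minor-allele frequency
#'   below `eaf_ambiguity` in both), otherwise drop with reason
#'   `"palindromic_ambiguous"`;
#' * `"drop_all"`: drop every palindromic SNP;
#' * `"keep"`: trust the reported alleles as being on the same strand.
#'
#' Exposure SNPs absent from the outcome are recorded as dropped rows
#' with reason `"not_in_outcome"` so selection audits stay complete.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param palindrome_policy see above.
#' @param eaf_ambiguity frequency cutoff for palindromic orientation;
#'   a palindromic SNP whose minor-allele frequency exceeds this value in
#'   either study (or whose frequency is missing) cannot be oriented.
#' @return an `mr_harmonized` data.frame, one row per exposure SNP, with
#'   `dropped`/`reason` bookkeeping.  Use [retained()] for the analysis
#'   rows.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "drop_all",
                                            "keep"),
                      eaf_ambiguity = 0.42) {
  stopifnot(inherits(exposure, "mr_sumstats"), inherits(outcome, "mr_sumstats"))
  palindrome_policy <- match.arg(palindrome_policy)

  e <- as.data.frame(exposure)
  o <- as.data.frame(outcome)
  idx <- match(e$snp_id, o$snp_id)
  shared <- !is.na(idx)
  if (!any(shared)) {
    warning("no SNPs shared between '", attr(exposure, "trait_name"),
            "' and '", attr(outcome, "trait_name"), "'")
  }

  n <- nrow(e)
  out <- data.frame(
    snp_id = e$snp_id, chrom = e$chrom, pos = e$pos,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf, n_exp = e$n,
    pvalue_exp = e$pvalue,
    beta_out = NA_real_, se_out = NA_real_, eaf_out = NA_real_,
    n_out = NA_real_,
    palindromic = .is_palindromic(e$effect_allele, e$other_allele),
    dropped = !shared,
    reason = ifelse(shared, NA_character_, "not_in_outcome"),
    stringsAsFactors = FALSE)

  if (any(shared)) {
    oe <- o[idx[shared], , drop = FALSE]
    ea <- e$effect_allele[shared]; oa <- e$other_allele[shared]
    o_ea <- oe$effect_allele;      o_oa <- oe$other_allele
    pal <- out$palindromic[shared]

    direct  <- o_ea == ea & o_oa == oa
    swapped <- o_ea == oa & o_oa == ea
    flip_d  <- .complement(o_ea) == ea & .complement(o_oa) == oa
    flip_s  <- .complement(o_ea) == oa & .complement(o_oa) == ea

    # action: 1 keep, -1 swap sign, 0 mismatch, NA decided by policy
    action <- rep(NA_real_, sum(shared))
    action[!pal & direct]              <- 1
    action[!pal & swapped]             <- -1
    action[!pal & !direct & !swapped & flip_d] <- 1
    action[!pal & !direct & !swapped & flip_s] <- -1
    action[!pal & is.na(action)]       <- 0

    reason <- rep(NA_character_, sum(shared))
    if (any(pal)) {
      pal_match <- direct | swapped | flip_d | flip_s
      if (palindrome_policy == "drop_all") {
        action[pal] <- 0
        reason[pal] <- "palindromic"
      } else if (palindrome_policy == "keep") {
        # reported alleles taken at face value: swapped labels still flip
        action[pal & (direct | flip_s)] <- 1
        action[pal & !direct & (swapped | flip_d)] <- -1
        action[pal & !pal_match] <- 0
      } else {
        maf_e <- pmin(out$eaf_exp[shared], 1 - out$eaf_exp[shared])
        maf_o <- pmin(oe$eaf, 1 - oe$eaf)
        orientable <- pal_match & !is.na(maf_e) & !is.na(maf_o) &
          maf_e <= eaf_ambiguity & maf_o <= eaf_ambiguity
        same_side <- (out$eaf_exp[shared] < 0.5) == (oe$eaf < 0.5)
        action[pal & orientable & same_side]  <- 1
        action[pal & orientable & !same_side] <- -1
        action[pal & !orientable] <- 0
        reason[pal & !orientable & pal_match] <- "palindromic_ambiguous"
      }
      reason[pal & action == 0 & is.na(reason)] <-
        if (palindrome_policy == "drop_all") "palindromic" else "allele_mismatch"
    }
    reason[action == 0 & is.na(reason)] <- "allele_mismatch"

    keep <- action != 0
    out$beta_out[shared][keep] <- action[keep] * oe$beta[keep]
    out$se_out[shared][keep]   <- oe$se[keep]
    out$eaf_out[shared][keep]  <- ifelse(action[keep] == 1, oe$eaf[keep],
                                         1 - oe$eaf[keep])
    out$n_out[shared][keep]    <- oe$n[keep]
    out$dropped[shared][!keep] <- TRUE
    out$reason[shared][!keep]  <- reason[!keep]
  }

  .new_harmonized(out, exposure, outcome)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s: %d retained, %d dropped\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              sum(!x$dropped), sum(x$dropped)))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
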