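## GWAS summary-statistics data model: a tibble with one row per biallelic
## autosomal SNP and trait-level metadata carried in attributes. This is the
## unit of exchange between the meta-analysis, instrument-selection and
## harmonisation steps.

SUMSTATS_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

VALID_ALLELES <- c("A", "C", "G", "T")

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a validated summary-statistics table
#'
#' Builds the per-SNP association table used throughout the pipeline: one
#' row per biallelic SNP with an effect allele, effect-allele frequency,
#' per-allele effect (log-odds ratio for a binary trait), its standard
#' error, p-value and sample size. Rows violating the record invariants
#' (non-ACGT or identical alleles, `se <= 0`, `eaf` outside `[0, 1]`,
#' p-value outside `(0, 1]`, duplicated `snp_id`) are dropped, not repaired;
#' the counts of dropped rows by reason are attached as the `"dropped"`
#' attribute and reported via a message. Alleles are upper-cased before
#' validation, so lowercase input is accepted. Indels and multi-allelic
#' records (allele strings longer than one base) fail the allele check and
#' are therefore rejected at this point.
#'
#' @param df Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`
#'   and optionally `n_studies`.
#' @param trait_name Name of the trait the statistics describe.
#' @param trait_type `"binary"` or `"quantitative"`; decides whether `beta`
#'   is a log-odds ratio or an effect in trait units.
#' @param genomic_lambda Optional genomic-control inflation factor already
#'   estimated for this table.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble of class `osteomr_sumstats` with attributes
#'   `trait_name`, `trait_type`, `genomic_lambda` and `dropped` (a named
#'   integer vector of exclusion counts by reason).
#' @export
#' @examples
#' sumstats(
#'   data.frame(
#'     snp_id = "rs1", chrom = "1", pos = 1000L,
#'     effect_allele = "a", other_allele = "g",
#'     eaf = 0.3, beta = 0.05, se = 0.01, pvalue = 1e-6, n = 50000
#'   ),
#'   trait_name = "fracture", trait_type = "binary"
#' )
sumstats <- function(df, trait_name = "trait", trait_type = c("binary", "quantitative"),
                     genomic_lambda = NA_real_, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "summary-statistics input lacks mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(df)
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  if (!"n_studies" %in% names(x)) x$n_studies <- NA_integer_

  dropped <- c(
    bad_allele = 0L, same_alleles = 0L, bad_se = 0L, bad_eaf = 0L,
    bad_pvalue = 0L, missing = 0L, duplicate_id = 0L
  )
  core <- x[, SUMSTATS_COLS]
  ok_complete <- complete.cases(core)
  dropped["missing"] <- sum(!ok_complete)
  x <- x[ok_complete, ]

  ok_allele <- x$effect_allele %in% VALID_ALLELES & x$other_allele %in% VALID_ALLELES
  dropped["bad_allele"] <- sum(!ok_allele)
  x <- x[ok_allele, ]

  ok_distinct <- x$effect_allele != x$other_allele
  dropped["same_alleles"] <- sum(!ok_distinct)
  x <- x[ok_distinct, ]

  ok_se <- x$se > 0
  dropped["bad_se"] <- sum(!ok_se)
  x <- x[ok_se, ]

  ok_eaf <- x$eaf >= 0 & x$eaf <= 1
  dropped["bad_eaf"] <- sum(!ok_eaf)
  x <- x[ok_eaf, ]

  ok_p <- x$pvalue > 0 & x$pvalue <= 1
  dropped["bad_pvalue"] <- sum(!ok_p)
  x <- x[ok_p, ]

  dup <- duplicated(x$snp_id)
  dropped["duplicate_id"] <- sum(dup)
  x <- x[!dup, ]

  n_dropped <- sum(dropped)
  if (n_dropped > 0 && !quiet) {
    why <- dropped[dropped > 0]
    inform(sprintf(
      "Dropped %d summary-statistics row(s): %s.", n_dropped,
      paste(sprintf("%s=%d", names(why), why), collapse = ", ")
    ))
  }

  structure(
    x,
    class = c("osteomr_sumstats", class(tibble::tibble())),
    trait_name = trait_name,
    trait_type = trait_type,
    genomic_lambda = genomic_lambda,
    dropped = dropped
  )
}

#' @export
print.osteomr_sumstats <- function(x, ...) {
  lam <- attr(x, "genomic_lambda")
  cat(sprintf(
    "<summary statistics: %s (%s), %d SNPs%s>\n",
    attr(x, "trait_name"), attr(x, "trait_type"), nrow(x),
    if (is.finite(lam)) sprintf(", lambda = %.3f", lam) else ""
  ))
  NextMethod()
}

## Column order written to disk and expected (after column_map renames) on
## read. Tab-delimited with a header; gzip handled transparently by readr.
SUMSTATS_FILE_COLS <- c(
  SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "effect_allele",
  OA = "other_allele", EAF = "eaf", BETA = "beta", SE = "se",
  P = "pvalue", N = "n"
)

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-delimited file with header columns `SNP, CHR, POS, EA, OA,
#' EAF, BETA, SE, P, N` (plus optional `N_STUDIES`), applies any renames in
#' `column_map`, and validates the rows through [sumstats()]. Files ending
#' in `.gz` are decompressed transparently.
#'
#' @param path Path to a tab-delimited text file (optionally gzipped).
#' @param column_map Optional named character vector mapping standard names
#'   to the file's column names, e.g. `c(SNP = "rsid", P = "pval")`.
#' @inheritParams sumstats
#' @return A validated [sumstats()] tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = "trait",
                          trait_type = c("binary", "quantitative"), quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort(sprintf("summary-statistics file not found: %s", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("summary-statistics file is empty: %s", path))

  wanted <- SUMSTATS_FILE_COLS
  file_names <- setNames(names(wanted), names(wanted))
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(wanted))
    if (length(unknown) > 0) {
      abort(paste0("column_map refers to unknown standard column(s): ",
                   paste(unknown, collapse = ", ")))
    }
    file_names[names(column_map)] <- unname(column_map)
  }
  missing <- setdiff(unname(file_names), names(raw))
  if (length(missing) > 0) {
    abort(paste0("mandatory column(s) absent from ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(setNames(
    lapply(unname(file_names), function(cn) raw[[cn]]),
    unname(wanted)
  ))
  if ("N_STUDIES" %in% names(raw)) out$n_studies <- as.integer(raw$N_STUDIES)
  sumstats(out, trait_name = trait_name, trait_type = trait_type, quiet = quiet)
}

#' Write summary statistics to a tab-delimited file
#'
#' Inverse of [read_sumstats()]: writes the standard `SNP, CHR, POS, EA, OA,
#' EAF, BETA, SE, P, N` header (plus `N_STUDIES` when populated). A write
#' followed by a read reproduces every field.
#'
#' @param x A [sumstats()] table.
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- tibble::as_tibble(x)[, SUMSTATS_FILE_COLS]
  names(out) <- names(SUMSTATS_FILE_COLS)
  if ("n_studies" %in% names(x) && any(!is.na(x$n_studies))) {
    out$N_STUDIES <- x$n_studies
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) ALLELE_COMPLEMENT[ea] == oa

#' Harmonise exposure and outcome summary statistics
#'
#' Builds the instrument set for two-sample Mendelian randomisation: SNPs
#' present in both tables (matched by `snp_id`) with the outcome effect
#' expressed for the exposure's effect allele. When the outcome's effect
#' allele equals the exposure's other allele the outcome beta is negated and
#' its frequency complemented; alleles that match only after strand
#' complementing are accepted likewise. Strand-ambiguous (A/T, C/G) SNPs
#' whose effect-allele frequency falls within `palindrome_eaf_window` of 0.5
#' in either table are excluded, since their strand cannot be resolved from
#' frequency; allele pairs irreconcilable even after complementing are
#' excluded. Exclusions are tallied by reason in the `"exclusions"`
#' attribute.
#'
#' @param exposure,outcome Validated [sumstats()] tables.
#' @param palindrome_eaf_window Half-width of the frequency window around
#'   0.5 inside which palindromic SNPs are dropped (default 0.08).
#' @return A tibble of class `osteomr_instruments` with columns `snp_id`,
#'   `bx`, `se_bx`, `by`, `se_by`, `eaf`, `pvalue_exposure`, and attributes
#'   `exposure_name`, `outcome_name`, `exposure_type`, `exclusions`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot_scalar(palindrome_eaf_window, "palindrome_eaf_window", 0, 0.5)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) abort("exposure and outcome share no SNPs; nothing to harmonise.")

  ex <- tibble::as_tibble(exposure)[match(shared, exposure$snp_id), ]
  ou <- tibble::as_tibble(outcome)[match(shared, outcome$snp_id), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  cea_y <- unname(ALLELE_COMPLEMENT[ea_y]); coa_y <- unname(ALLELE_COMPLEMENT[oa_y])

  aligned <- (ea_y == ea_x & oa_y == oa_x) | (cea_y == ea_x & coa_y == oa_x)
  ## for palindromic SNPs both readings match; exact alignment takes priority
  swapped <- !aligned &
    ((ea_y == oa_x & oa_y == ea_x) | (cea_y == oa_x & coa_y == ea_x))

  palin <- is_palindromic(ea_x, oa_x)
  ambiguous <- palin &
    (abs(ex$eaf - 0.5) < palindrome_eaf_window |
       abs(ou$eaf - 0.5) < palindrome_eaf_window)

  reason <- rep(NA_character_, length(shared))
  reason[!(aligned | swapped)] <- "irreconcilable_alleles"
  reason[is.na(reason) & ambiguous] <- "palindromic"

  keep <- is.na(reason)
  by <- ifelse(swapped, -ou$beta, ou$beta)

  out <- tibble::tibble(
    snp_id = shared[keep],
    bx = ex$beta[keep],
    se_bx = ex$se[keep],
    by = by[keep],
    se_by = ou$se[keep],
    eaf = ex$eaf[keep],
    pvalue_exposure = ex$pvalue[keep]
  )
  exclusions <- tibble::tibble(snp_id = shared[!keep], reason = reason[!keep])
  if (nrow(out) == 0) abort("no SNPs survive harmonisation.")

  structure(
    out,
    class = c("osteomr_instruments", class(tibble::tibble())),
    exposure_name = attr(exposure, "trait_name") %||% "exposure",
    outcome_name = attr(outcome, "trait_name") %||% "outcome",
    exposure_type = attr(exposure, "trait_type") %||% "quantitative",
    exclusions = exclusions
  )
}

#' @export
print.osteomr_instruments <- function(x, ...) {
  cat(sprintf(
    "<harmonised instruments: %s -> %s, %d SNPs (%d excluded)>\n",
    attr(x, "exposure_name"), attr(x, "outcome_name"), nrow(x),
    nrow(attr(x, "exclusions"))
  ))
  NextMethod()
}

## Internal: build an instrument set directly from effect vectors, used by
## the simulators and tests to skip file round trips.
new_instruments <- function(snp_id, bx, se_bx, by, se_by,
                            exposure_name = "exposure",
                            outcome_name = "outcome",
                            exposure_type = "quantitative") {
  structure(
    tibble::tibble(
      snp_id = snp_id, bx = bx, se_bx = se_bx, by = by, se_by = se_by,
      eaf = NA_real_, pvalue_exposure = two_sided_p(bx / se_bx)
    ),
    class = c("osteomr_instruments", class(tibble::tibble())),
    exposure_name = exposure_name,
    outcome_name = outcome_name,
    exposure_type = exposure_type,
    exclusions = tibble::tibble(snp_id = character(), reason = character())
  )
}
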