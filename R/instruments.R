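## Instrument selection for Mendelian randomisation: the significance and
## common-variant gates, greedy LD clumping, and the binary-exposure
## per-doubling rescaling.

#' Significance and frequency gates for MR instruments
#'
#' Keeps SNPs strongly associated with the risk factor (`pvalue <
#' p_threshold`) and common (minor allele frequency strictly above
#' `maf_threshold`), the two explicit conditions behind the relevance
#' assumption of the instrumental-variable design.
#'
#' @param x A [sumstats()] table for the exposure.
#' @param p_threshold Association threshold (default `5e-8`, genome-wide
#'   significance).
#' @param maf_threshold Minor-allele-frequency floor, exclusive (default
#'   0.05: "common variants").
#' @return The surviving rows; an empty result triggers a warning, not an
#'   error.
#' @export
select_instruments <- function(x, p_threshold = 5e-8, maf_threshold = 0.05) {
  maf <- pmin(x$eaf, 1 - x$eaf)
  out <- x[x$pvalue < p_threshold & maf > maf_threshold, ]
  if (nrow(out) == 0) {
    warn(sprintf(
      "no SNPs pass p < %g and MAF > %g; returning an empty table.",
      p_threshold, maf_threshold
    ))
  }
  out
}

validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) abort("LD input must be a square matrix.")
  if (is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld))) {
    abort("LD matrix needs identical SNP-id row and column names.")
  }
  if (any(ld < 0 | ld > 1)) abort("r-squared entries must lie in [0, 1].")
  if (any(abs(diag(ld) - 1) > 1e-8)) abort("LD matrix diagonal must be 1.")
  if (max(abs(ld - t(ld))) > 1e-8) abort("LD matrix must be symmetric.")
  invisible(ld)
}

#' Read / write a square r-squared LD matrix
#'
#' Tab-delimited square numeric matrix with SNP ids as the header row and
#' first column.
#'
#' @param path File path.
#' @return `read_ld_matrix()`: a named symmetric matrix of squared
#'   correlations.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1])
  rownames(m) <- ids
  colnames(m) <- names(raw)[-1]
  validate_ld_matrix(m)
  m
}

#' @rdname read_ld_matrix
#' @param ld Named square r-squared matrix.
#' @export
write_ld_matrix <- function(ld, path) {
  validate_ld_matrix(ld)
  out <- tibble::as_tibble(ld)
  out <- dplyr::bind_cols(tibble::tibble(SNP = rownames(ld)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Greedy LD clumping of significant SNPs
#'
#' Groups SNPs in linkage disequilibrium and keeps only the most significant
#' representative of each group: SNPs are visited in ascending p-value (ties
#' broken lexicographically by `snp_id` for determinism) and a SNP is
#' retained only if its r-squared with every previously retained SNP is at
#' most `r2_threshold`. The grouping criterion is `r^2 > r2_threshold`, so
#' the boundary value is treated as independent and retained.
#'
#' @param x A [sumstats()] table (typically the output of
#'   [select_instruments()]).
#' @param ld Named square r-squared matrix covering every SNP in `x`.
#' @param r2_threshold Maximum squared correlation tolerated between kept
#'   SNPs (default 0.05).
#' @return The retained rows, ordered by ascending p-value.
#' @export
greedy_clump <- function(x, ld, r2_threshold = 0.05) {
  validate_ld_matrix(ld)
  missing <- setdiff(x$snp_id, rownames(ld))
  if (length(missing) > 0) {
    abort(paste0("SNP(s) absent from the LD matrix: ",
                 paste(missing, collapse = ", ")))
  }
  ord <- order(x$pvalue, x$snp_id)
  x <- x[ord, ]
  kept <- character(0)
  for (id in x$snp_id) {
    if (all(ld[id, kept] <= r2_threshold)) kept <- c(kept, id)
  }
  x[x$snp_id %in% kept, ]
}

#' Rescale a binary-exposure causal estimate to the per-doubling scale
#'
#' A causal log-odds estimate expressed per unit log-odds of a binary
#' exposure is hard to interpret; multiplying the log effect (and its
#' standard error and interval bounds) by 0.693 re-expresses it per doubling
#' of the odds of exposure susceptibility. The z-statistic, and hence the
#' p-value, is unchanged.
#'
#' @param estimate An `osteomr_mr` estimate (see [mr_ivw()]) whose
#'   `exposure_type` is `"binary"`.
#' @param level Confidence level for the recomputed interval.
#' @return The estimate with `beta`, `se` and the odds-ratio columns on the
#'   per-doubling scale.
#' @export
rescale_binary_exposure <- function(estimate, level = 0.95) {
  if (!all(estimate$exposure_type == "binary")) {
    abort("rescale_binary_exposure() applies to binary exposures only.")
  }
  z <- z_quantile(level)
  estimate$beta <- estimate$beta * DOUBLING_CONSTANT
  estimate$se <- estimate$se * DOUBLING_CONSTANT
  estimate$or <- exp(estimate$beta)
  estimate$ci_low <- exp(estimate$beta - z * estimate$se)
  estimate$ci_high <- exp(estimate$beta + z * estimate$se)
  estimate
}
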