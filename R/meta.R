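## Fixed-effects inverse-variance meta-analysis with per-study genomic
## control: the discovery -> replication -> combined chain of a staged
## case-control GWAS.

#' Recover a log-odds standard error from a printed confidence interval
#'
#' Association tables print odds ratios with confidence intervals rather
#' than standard errors; this inverts the interval under log-normality:
#' `se = (ln(ci_high) - ln(ci_low)) / (2 z)` with `z` the standard-normal
#' quantile at `(1 + level)/2`. Vectorised over all arguments.
#'
#' @param or_point Odds-ratio point estimate(s).
#' @param ci_low,ci_high Confidence bounds on the odds-ratio scale.
#' @param level Confidence level of the printed interval (default 0.95).
#' @return Standard error(s) of the log-odds ratio.
#' @export
#' @examples
#' se_from_ci(1.08, 1.06, 1.10) # the published rs2908007 discovery cell
se_from_ci <- function(or_point, ci_low, ci_high, level = 0.95) {
  stopifnot_scalar(level, "level", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  bad <- !(ci_low > 0 & ci_low <= or_point & or_point <= ci_high)
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf(
      "confidence bounds must satisfy 0 < ci_low <= or_point <= ci_high (violated for %d value(s)).",
      sum(bad, na.rm = TRUE)
    ))
  }
  (log(ci_high) - log(ci_low)) / (2 * z_quantile(level))
}

#' Recover a log-odds standard error from a printed p-value
#'
#' Fallback for table cells whose printed interval is internally
#' inconsistent (e.g. a degenerate or mis-typeset interval): under a Wald
#' test, `se = |ln(or)| / qnorm(p/2, lower.tail = FALSE)`.
#'
#' @param or_point Odds-ratio point estimate(s).
#' @param pvalue Two-sided p-value(s) in (0, 1).
#' @return Standard error(s) of the log-odds ratio.
#' @export
se_from_p <- function(or_point, pvalue) {
  if (any(pvalue <= 0 | pvalue >= 1)) abort("pvalue must lie in (0, 1).")
  abs(log(or_point)) / qnorm(pvalue / 2, lower.tail = FALSE)
}

#' Genomic-control correction of a summary-statistics table
#'
#' Estimates the genomic inflation factor `lambda` as the median association
#' chi-square, `(beta/se)^2`, divided by the chi-square(1) median (0.4549...).
#' When `lambda > 1` every standard error is inflated by `sqrt(lambda)` and
#' p-values are recomputed from the corrected z-scores; `lambda <= 1` leaves
#' the statistics untouched. The estimate is stored in the table's
#' `genomic_lambda` attribute either way. Applied per study before pooling,
#' never to a pooled result.
#'
#' @param x A [sumstats()] table; a warning is issued below 100 SNPs, where
#'   the median is a poor inflation estimate.
#' @return The corrected table with `genomic_lambda` set.
#' @export
genomic_control <- function(x) {
  if (nrow(x) < 100) {
    warn(sprintf("genomic control on only %d SNPs; lambda is unstable.", nrow(x)))
  }
  chi2 <- (x$beta / x$se)^2
  lambda <- median(chi2) / CHISQ1_MEDIAN
  if (lambda > 1) {
    x$se <- x$se * sqrt(lambda)
    x$pvalue <- two_sided_p(x$beta / x$se)
  }
  attr(x, "genomic_lambda") <- lambda
  x
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-stage (or per-cohort) log-odds estimates with precision
#' weights: `beta = sum(b_i/se_i^2) / sum(1/se_i^2)`,
#' `se = 1/sqrt(sum(1/se_i^2))`. Heterogeneity is summarised by Cochran's
#' `Q = sum((b_i - beta)^2 / se_i^2)` and `I^2 = max(0, (Q - (k-1))/Q) * 100`.
#' The confidence interval is reported on the odds-ratio scale.
#'
#' @param estimates Data frame with columns `beta` and `se` (one row per
#'   stage/cohort); an optional `label` column is ignored by the arithmetic.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble of class `osteomr_meta` with columns `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `pvalue`, `q_stat`, `i2`, `k`.
#' @export
#' @examples
#' fixed_effects_meta(data.frame(beta = c(0.05, 0.04), se = c(0.01, 0.008)))
fixed_effects_meta <- function(estimates, level = 0.95) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    abort("at least one stage estimate is required.")
  }
  b <- estimates$beta
  s <- estimates$se
  if (any(!is.finite(b)) || any(!is.finite(s)) || any(s <= 0)) {
    abort("every estimate needs a finite beta and a positive se.")
  }
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- z_quantile(level)
  q <- sum(w * (b - beta)^2)
  k <- length(b)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  structure(
    tibble::tibble(
      beta = beta, se = se, or = exp(beta),
      ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
      pvalue = two_sided_p(beta / se),
      q_stat = q, i2 = i2, k = k
    ),
    class = c("osteomr_meta", class(tibble::tibble()))
  )
}

#' Per-SNP meta-analysis across studies
#'
#' Pools several summary-statistics tables SNP by SNP with
#' [fixed_effects_meta()], after optional per-study genomic control and
#' after aligning each study's effect allele to the first study that reports
#' the SNP (swapped alleles flip the beta and complement the frequency).
#' SNPs whose alleles are irreconcilable with the reference orientation in
#' some study are pooled over the reconcilable studies only.
#'
#' @param tables List of [sumstats()] tables (one per study).
#' @param gc Apply [genomic_control()] to each study first (default TRUE).
#' @return Tibble with one row per SNP: positions, reference alleles,
#'   precision-weighted `eaf`, pooled `beta`, `se`, `pvalue`, heterogeneity
#'   `q_stat`/`i2`, `n_studies`, and total `n`.
#' @export
meta_analyse <- function(tables, gc = TRUE) {
  if (length(tables) == 0) abort("no studies supplied.")
  if (gc) tables <- lapply(tables, genomic_control)
  stacked <- dplyr::bind_rows(lapply(tables, tibble::as_tibble), .id = "study")

  stacked |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::group_modify(function(g, key) {
      ea <- g$effect_allele[1]
      oa <- g$other_allele[1]
      aligned <- g$effect_allele == ea & g$other_allele == oa
      swapped <- g$effect_allele == oa & g$other_allele == ea
      g <- g[aligned | swapped, ]
      flip <- g$effect_allele != ea
      beta <- ifelse(flip, -g$beta, g$beta)
      eaf <- ifelse(flip, 1 - g$eaf, g$eaf)
      pooled <- fixed_effects_meta(data.frame(beta = beta, se = g$se))
      tibble::tibble(
        chrom = g$chrom[1], pos = g$pos[1],
        effect_allele = ea, other_allele = oa,
        eaf = sum(eaf / g$se^2) / sum(1 / g$se^2),
        beta = pooled$beta, se = pooled$se, pvalue = pooled$pvalue,
        q_stat = pooled$q_stat, i2 = pooled$i2,
        n_studies = nrow(g), n = sum(g$n)
      )
    }) |>
    dplyr::ungroup()
}

#' Genome-wide significance filter
#'
#' Keeps meta-analysed SNPs that pass the three reporting gates of a staged
#' GWAS: association below the genome-wide threshold, presence in more than
#' `min_studies_exclusive` studies (strict inequality), and minor allele
#' frequency at or above `maf_threshold`. Input order is preserved.
#'
#' @param meta Tibble with columns `pvalue`, `n_studies` and either `maf` or
#'   `eaf` (from which MAF is derived as `min(eaf, 1 - eaf)`).
#' @param p_threshold Genome-wide significance level (default `5e-8`).
#' @param min_studies_exclusive SNPs must be present in strictly more than
#'   this many studies (default 2).
#' @param maf_threshold Minimum minor-allele frequency (default 0.01,
#'   inclusive).
#' @return The surviving rows, order preserved.
#' @export
gws_filter <- function(meta, p_threshold = 5e-8, min_studies_exclusive = 2,
                       maf_threshold = 0.01) {
  maf <- if ("maf" %in% names(meta)) meta$maf else pmin(meta$eaf, 1 - meta$eaf)
  keep <- meta$pvalue < p_threshold &
    meta$n_studies > min_studies_exclusive &
    maf >= maf_threshold
  meta[keep, ]
}
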