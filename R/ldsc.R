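## LD score regression: single-trait heritability and cross-trait genetic
## covariance / correlation from GWAS z-scores, with block-jackknife
## standard errors. Regression weights are the single-step 1/l_j
## heteroskedasticity proxy; the original method's iterative weighting is
## deliberately not reproduced.

#' Per-SNP LD scores from an r-squared matrix
#'
#' The LD score of SNP `j` is the sum of its squared correlations with all
#' SNPs in the reference, including itself: `l_j = sum_k r2_jk`, so a SNP
#' in no LD has score 1.
#'
#' @param ld Named square r-squared matrix (see [read_ld_matrix()]).
#' @param m Total number of SNPs `M` used as the polygenicity denominator;
#'   defaults to the matrix dimension.
#' @return A tibble of class `osteomr_ldscores` with columns `snp_id`,
#'   `ell` and attribute `m`.
#' @export
ld_scores <- function(ld, m = nrow(ld)) {
  validate_ld_matrix(ld)
  if (m < nrow(ld)) abort("`m` cannot be smaller than the number of scored SNPs.")
  structure(
    tibble::tibble(snp_id = rownames(ld), ell = unname(rowSums(ld))),
    class = c("osteomr_ldscores", class(tibble::tibble())),
    m = m
  )
}

new_ld_scores <- function(snp_id, ell, m) {
  structure(
    tibble::tibble(snp_id = snp_id, ell = ell),
    class = c("osteomr_ldscores", class(tibble::tibble())),
    m = m
  )
}

## Single weighted regression of y on ell; returns c(intercept, slope).
## Weights 1/ell down-weight high-LD SNPs whose chi-square has larger
## sampling variance.
wls_on_ell <- function(y, ell) {
  w <- 1 / ell
  sw <- sum(w); swx <- sum(w * ell); swxx <- sum(w * ell^2)
  swy <- sum(w * y); swxy <- sum(w * ell * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  c(intercept = intercept, slope = slope)
}

jackknife_blocks <- function(n_snps, n_blocks) {
  if (n_blocks < 2) abort("the block jackknife needs at least 2 blocks.")
  if (n_snps < n_blocks) abort("fewer SNPs than jackknife blocks.")
  split(seq_len(n_snps), cut(seq_len(n_snps), n_blocks, labels = FALSE))
}

## Delete-one-block jackknife of an arbitrary statistic fn(idx) over
## contiguous SNP blocks; returns list(estimate, se) where estimate is the
## full-sample value.
block_jackknife <- function(n_snps, n_blocks, fn) {
  blocks <- jackknife_blocks(n_snps, n_blocks)
  full <- fn(seq_len(n_snps))
  loo <- vapply(blocks, function(b) fn(setdiff(seq_len(n_snps), b)),
                numeric(length(full)))
  loo <- matrix(loo, nrow = length(full))
  nb <- length(blocks)
  ## pseudo-value jackknife variance
  se <- sqrt((nb - 1) / nb * rowSums((loo - rowMeans(loo))^2))
  list(estimate = full, se = se)
}

new_ldsc_fit <- function(quantity, estimate, se, intercept, intercept_se,
                         n_blocks, m, extra = NULL) {
  out <- tibble::tibble(
    quantity = quantity, estimate = estimate, se = se,
    pvalue = two_sided_p(estimate / se),
    intercept = intercept, intercept_se = intercept_se,
    n_blocks = as.integer(n_blocks), m = as.integer(m)
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out, class = c("osteomr_ldsc", class(tibble::tibble())))
}

#' Single-trait LD score regression for SNP heritability
#'
#' Regresses per-SNP association chi-squares `z^2` on LD scores with
#' weights `1/l_j`. Under a polygenic model `E[chi2_j] = 1 + N h2 l_j / M`,
#' so the heritability estimate is `slope * M / N` and the intercept
#' (expected 1 without confounding) is the stratification diagnostic.
#' Standard errors come from a delete-one-block jackknife over contiguous
#' SNP blocks.
#'
#' @param z Per-SNP z-scores, aligned with `scores`.
#' @param n GWAS sample size.
#' @param scores [ld_scores()] for the same SNPs.
#' @param n_blocks Number of contiguous jackknife blocks (default 20).
#' @return A one-row `osteomr_ldsc` tibble with `quantity = "h2"`.
#' @export
h2_regression <- function(z, n, scores, n_blocks = 20) {
  if (length(z) != nrow(scores)) abort("z-scores and LD scores must be aligned.")
  m <- attr(scores, "m")
  chi2 <- z^2
  ell <- scores$ell
  fit_fn <- function(idx) {
    co <- wls_on_ell(chi2[idx], ell[idx])
    c(h2 = unname(co["slope"]) * m / n, intercept = unname(co["intercept"]))
  }
  jk <- block_jackknife(length(z), n_blocks, fit_fn)
  new_ldsc_fit("h2", jk$estimate["h2"], jk$se[1],
               jk$estimate["intercept"], jk$se[2], n_blocks, m)
}

#' Cross-trait LD score regression for genetic correlation
#'
#' Regresses the per-SNP z-score product `z1 * z2` on LD scores (weights
#' `1/l_j`): the slope estimates `sqrt(N1 N2) * gcov / M` where `gcov` is
#' the genetic covariance, while the intercept absorbs the correlation
#' induced by overlapping samples. The genetic correlation is
#' `rg = gcov / sqrt(h2_1 * h2_2)` with heritabilities from
#' [h2_regression()] on each trait. The whole three-regression pipeline is
#' jackknifed jointly over contiguous blocks. Estimates outside `[-1, 1]`
#' are clamped with a warning (the raw value is kept in `rg_raw`); a
#' non-positive heritability in either trait leaves `rg` undefined with the
#' reason recorded.
#'
#' @param z1,z2 Per-SNP z-scores for the two traits, aligned with `scores`.
#' @param n1,n2 The two GWAS sample sizes.
#' @param n_shared Number of overlapping samples (annotation only; overlap
#'   is absorbed by the intercept, not subtracted).
#' @param scores [ld_scores()] for the same SNPs.
#' @param n_blocks Number of contiguous jackknife blocks (default 20).
#' @param n_tests Bonferroni family size for the attached significance
#'   flag (default 12).
#' @return A one-row `osteomr_ldsc` tibble with `quantity = "rg"`, columns
#'   `gcov`, `h2_1`, `h2_2`, `rg_raw`, `reason` and
#'   `significant_after_bonferroni`.
#' @export
rg_regression <- function(z1, z2, n1, n2, n_shared = 0, scores,
                          n_blocks = 20, n_tests = 12) {
  if (length(z1) != length(z2) || length(z1) != nrow(scores)) {
    abort("z-scores of both traits and LD scores must be aligned.")
  }
  m <- attr(scores, "m")
  ell <- scores$ell
  fit_fn <- function(idx) {
    co_x <- wls_on_ell(z1[idx]^2, ell[idx])
    co_y <- wls_on_ell(z2[idx]^2, ell[idx])
    co_xy <- wls_on_ell((z1 * z2)[idx], ell[idx])
    h2_1 <- unname(co_x["slope"]) * m / n1
    h2_2 <- unname(co_y["slope"]) * m / n2
    gcov <- unname(co_xy["slope"]) * m / sqrt(n1 * n2)
    rg <- if (h2_1 > 0 && h2_2 > 0) gcov / sqrt(h2_1 * h2_2) else NA_real_
    c(rg = rg, gcov = gcov, h2_1 = h2_1, h2_2 = h2_2,
      intercept = unname(co_xy["intercept"]))
  }
  jk <- block_jackknife(length(z1), n_blocks, fit_fn)
  est <- jk$estimate
  reason <- NA_character_
  rg_raw <- est["rg"]
  rg <- rg_raw
  if (est["h2_1"] <= 0 || est["h2_2"] <= 0 || is.na(rg_raw)) {
    reason <- "non-positive heritability estimate"
    rg <- NA_real_
  } else if (abs(rg_raw) > 1) {
    warn(sprintf("genetic correlation %.3f outside [-1, 1]; clamped.", rg_raw))
    rg <- sign(rg_raw) * 1
  }
  out <- new_ldsc_fit(
    "rg", unname(rg), unname(jk$se[1]),
    unname(est["intercept"]), unname(jk$se[5]), n_blocks, m,
    extra = tibble::tibble(
      gcov = unname(est["gcov"]), h2_1 = unname(est["h2_1"]),
      h2_2 = unname(est["h2_2"]), rg_raw = unname(rg_raw),
      n_shared = n_shared, reason = reason
    )
  )
  bonferroni_flag(out, n_tests)
}
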