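## Two-sample Mendelian randomisation estimator suite: Wald ratio, fixed-
## effects IVW, MR-Egger, weighted and penalised weighted medians, power
## calculation and Bonferroni flagging.

new_mr_estimate <- function(method, beta, se, n_snps,
                            exposure_type = "quantitative",
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_p = NA_real_, level = 0.95) {
  z <- z_quantile(level)
  structure(
    tibble::tibble(
      method = method,
      beta = beta,
      se = se,
      or = exp(beta),
      ci_low = exp(beta - z * se),
      ci_high = exp(beta + z * se),
      pvalue = two_sided_p(beta / se),
      intercept = intercept,
      intercept_se = intercept_se,
      intercept_p = intercept_p,
      n_snps = as.integer(n_snps),
      exposure_type = exposure_type,
      significant_after_bonferroni = NA
    ),
    class = c("osteomr_mr", class(tibble::tibble()))
  )
}

instrument_cols <- function(instruments) {
  needed <- c("bx", "se_bx", "by", "se_by")
  if (!all(needed %in% names(instruments))) {
    abort("instruments need columns bx, se_bx, by, se_by (see harmonize()).")
  }
  if (any(instruments$se_bx <= 0) || any(instruments$se_by <= 0)) {
    abort("instrument standard errors must be positive.")
  }
  instruments
}

exposure_type_of <- function(instruments) {
  attr(instruments, "exposure_type") %||% "quantitative"
}

#' Wald ratio causal estimate for a single instrument
#'
#' The per-SNP causal estimate `by / bx` with first-order delta-method
#' standard error `se_by / |bx|` (the uncertainty in the instrument-exposure
#' effect is ignored, consistent with inverse-variance weighting by the
#' outcome precision). The second-order expansion, which adds the
#' `by^2 se_bx^2 / bx^4` term, is available via `second_order = TRUE`.
#'
#' @param bx,se_bx SNP-exposure effect and its standard error.
#' @param by,se_by SNP-outcome effect and its standard error.
#' @param second_order Use the second-order delta-method standard error.
#' @param exposure_type `"binary"` or `"quantitative"` (annotation only).
#' @return A one-row `osteomr_mr` tibble.
#' @export
#' @examples
#' wald_ratio(bx = 0.1, se_bx = 0.01, by = 0.02, se_by = 0.005)
wald_ratio <- function(bx, se_bx, by, se_by, second_order = FALSE,
                       exposure_type = "quantitative") {
  if (bx == 0) abort("the Wald ratio is undefined for bx = 0.")
  beta <- by / bx
  se <- if (second_order) {
    sqrt(se_by^2 / bx^2 + by^2 * se_bx^2 / bx^4)
  } else {
    se_by / abs(bx)
  }
  new_mr_estimate("wald", beta, se, 1L, exposure_type)
}

ivw_weights <- function(instruments, second_order = FALSE) {
  v <- if (second_order) {
    instruments$se_by^2 / instruments$bx^2 +
      instruments$by^2 * instruments$se_bx^2 / instruments$bx^4
  } else {
    instruments$se_by^2 / instruments$bx^2
  }
  1 / v
}

#' Inverse-variance weighted causal estimate
#'
#' Precision-weighted pooling of per-SNP Wald ratios, algebraically the
#' zero-intercept weighted regression of outcome effects on exposure
#' effects with weights `1/se_by^2`:
#' `beta = sum(bx by / se_by^2) / sum(bx^2 / se_by^2)`,
#' `se = 1 / sqrt(sum(bx^2 / se_by^2))`. Fixed effects: no overdispersion
#' scaling is applied.
#'
#' @param instruments A [harmonize()]d instrument set (columns `bx`,
#'   `se_bx`, `by`, `se_by`).
#' @param second_order Use second-order Wald weights instead of the
#'   first-order default.
#' @param level Confidence level.
#' @return A one-row `osteomr_mr` tibble.
#' @export
mr_ivw <- function(instruments, second_order = FALSE, level = 0.95) {
  instruments <- instrument_cols(instruments)
  if (nrow(instruments) == 0) abort("at least one instrument is required.")
  w <- ivw_weights(instruments, second_order)
  r <- instruments$by / instruments$bx
  beta <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_mr_estimate("ivw", beta, se, nrow(instruments),
                  exposure_type_of(instruments), level = level)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept and weights `1/se_by^2`. Instruments are first oriented
#' so that every `bx` is non-negative (flipping `bx` and `by` jointly),
#' which makes the intercept an estimate of average directional pleiotropy;
#' the slope is the causal estimate. Standard errors come from the
#' weighted-least-squares information matrix without residual scaling,
#' matching the fixed-effects IVW convention. Requires more than two
#' instruments, otherwise the intercept and slope are unidentified beyond
#' an exact fit.
#'
#' @inheritParams mr_ivw
#' @return A one-row `osteomr_mr` tibble with `intercept`, `intercept_se`
#'   and `intercept_p` populated.
#' @export
mr_egger <- function(instruments, level = 0.95) {
  instruments <- instrument_cols(instruments)
  k <- nrow(instruments)
  if (k <= 2) abort("MR-Egger regression needs more than two genetic variants.")
  flip <- sign(instruments$bx)
  flip[flip == 0] <- 1
  bx <- instruments$bx * flip
  by <- instruments$by * flip
  w <- 1 / instruments$se_by^2

  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) abort("instrument exposure effects are collinear; Egger fit is singular.")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  se_slope <- sqrt(sw / det)
  se_intercept <- sqrt(swxx / det)

  new_mr_estimate(
    "egger", slope, se_slope, k, exposure_type_of(instruments),
    intercept = intercept, intercept_se = se_intercept,
    intercept_p = two_sided_p(intercept / se_intercept),
    level = level
  )
}

## Weighted median of ratios r with weights w, midpoint convention:
## with normalised weights sorted by ratio, the cumulative weight at ratio
## j is taken at the interval midpoint s'_j = s_j - w_j/2 and the estimate
## interpolates linearly between the ratios bracketing 0.5.
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  approx(s, r, xout = 0.5, ties = "ordered")$y
}

median_bootstrap_se <- function(instruments, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (is.null(seed)) abort("a seed is required for the bootstrap standard error.")
  withr::with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(instruments), instruments$bx, instruments$se_bx)
      by <- rnorm(nrow(instruments), instruments$by, instruments$se_by)
      point_fun(bx, instruments$se_bx, by, instruments$se_by)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted median causal estimate
#'
#' The weighted median of per-SNP Wald ratios with inverse-variance weights
#' `bx^2/se_by^2`, consistent when instruments carrying at least half of
#' the weight are valid. The point estimate uses the midpoint-interpolation
#' convention (see Details); the standard error is the standard deviation
#' of `n_boot` parametric-bootstrap replicates in which `bx` and `by` are
#' redrawn from normal distributions centred on their estimates.
#'
#' @details With normalised weights sorted by ratio, cumulative weight
#' `s_j` and midpoints `s'_j = s_j - w_j/2`, the estimate interpolates
#' linearly between the two ratios whose midpoints bracket 0.5.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of parametric bootstrap replicates (default 1000).
#'   `n_boot = 0` skips the bootstrap and reports `NA` standard error and
#'   p-value (useful inside simulation loops that only need the point
#'   estimate).
#' @param seed Seed for the bootstrap; mandatory when `n_boot > 0`.
#' @return A one-row `osteomr_mr` tibble.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL,
                               level = 0.95) {
  instruments <- instrument_cols(instruments)
  if (nrow(instruments) < 3) abort("the weighted median needs at least three instruments.")
  point <- function(bx, se_bx, by, se_by) {
    weighted_median_point(by / bx, bx^2 / se_by^2)
  }
  beta <- point(instruments$bx, instruments$se_bx,
                instruments$by, instruments$se_by)
  se <- median_bootstrap_se(instruments, point, n_boot, seed)
  new_mr_estimate("wmedian", beta, se, nrow(instruments),
                  exposure_type_of(instruments), level = level)
}

penalized_weights <- function(bx, se_bx, by, se_by, penalty_scale) {
  r <- by / bx
  w <- bx^2 / se_by^2
  beta_ivw <- sum(w * r) / sum(w)
  q_j <- w * (r - beta_ivw)^2
  p_j <- pchisq(q_j, df = 1, lower.tail = FALSE)
  w * pmin(1, penalty_scale * p_j)
}

#' Penalised weighted median causal estimate
#'
#' The weighted median after down-weighting heterogeneous instruments:
#' each SNP's contribution `Q_j = w_j (r_j - beta_IVW)^2` to Cochran's Q is
#' referred to a chi-square(1) upper-tail probability `q_j`, and its weight
#' is multiplied by `min(1, penalty_scale * q_j)`. Outlying (pleiotropic)
#' ratios receive near-zero weight while concordant ratios are unaffected,
#' so on homogeneous input the estimate equals [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param penalty_scale Multiplier on the heterogeneity tail probability
#'   (default 20; penalties bite once `q_j < 1/penalty_scale`).
#' @return A one-row `osteomr_mr` tibble.
#' @export
mr_penalized_weighted_median <- function(instruments, n_boot = 1000,
                                         seed = NULL, penalty_scale = 20,
                                         level = 0.95) {
  instruments <- instrument_cols(instruments)
  if (nrow(instruments) < 3) abort("the penalised weighted median needs at least three instruments.")
  point <- function(bx, se_bx, by, se_by) {
    weighted_median_point(by / bx, penalized_weights(bx, se_bx, by, se_by, penalty_scale))
  }
  beta <- point(instruments$bx, instruments$se_bx,
                instruments$by, instruments$se_by)
  se <- median_bootstrap_se(instruments, point, n_boot, seed)
  new_mr_estimate("pwmedian", beta, se, nrow(instruments),
                  exposure_type_of(instruments), level = level)
}

#' Statistical power of a two-sample MR analysis with a binary outcome
#'
#' Closed-form normal approximation: the non-centrality of the causal test
#' is `z_ncp = ln(target_or) * sqrt(n_outcome * r2_gx * K (1 - K))` with
#' `K` the outcome case fraction and `r2_gx` the variance in the exposure
#' explained by the instruments; the two-sided power at size `alpha` is
#' `pnorm(z_ncp - z_{1-alpha/2}) + pnorm(-z_ncp - z_{1-alpha/2})`.
#'
#' @param alpha Test size (e.g. `3.3e-3` after Bonferroni correction for
#'   15 risk factors).
#' @param n_outcome Total outcome-study sample size.
#' @param case_fraction Outcome case fraction `K` in (0, 1).
#' @param r2_gx Variance of the exposure explained by the instruments, in
#'   `[0, 1]`.
#' @param target_or Odds ratio per exposure standard deviation to detect.
#' @return Power as a fraction in `[0, 1]`.
#' @export
#' @examples
#' mr_power(alpha = 3.3e-3, n_outcome = 1e5, case_fraction = 0.5,
#'          r2_gx = 0.05, target_or = 1.15)
mr_power <- function(alpha, n_outcome, case_fraction, r2_gx, target_or) {
  stopifnot_scalar(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(case_fraction, "case_fraction", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(r2_gx, "r2_gx", 0, 1)
  stopifnot_scalar(n_outcome, "n_outcome", 1)
  stopifnot_scalar(target_or, "target_or", 0, strict_lower = TRUE)
  z_crit <- qnorm(1 - alpha / 2)
  z_ncp <- log(target_or) * sqrt(n_outcome * r2_gx * case_fraction * (1 - case_fraction))
  pnorm(z_ncp - z_crit) + pnorm(-z_ncp - z_crit)
}

#' Flag estimates significant after Bonferroni correction
#'
#' Sets `significant_after_bonferroni = pvalue < 0.05 / n_tests` (strict
#' inequality) on a table of MR estimates; with `n_tests = 15` the
#' threshold is 3.3e-3.
#'
#' @param results Tibble of MR estimates with a `pvalue` column.
#' @param n_tests Number of exposures tested.
#' @param alpha Family-wise error rate before division (default 0.05).
#' @return `results` with the flag column populated.
#' @export
bonferroni_flag <- function(results, n_tests, alpha = 0.05) {
  stopifnot_scalar(n_tests, "n_tests", 1)
  results$significant_after_bonferroni <- results$pvalue < alpha / n_tests
  results
}

#' Run the full MR estimator suite on one instrument set
#'
#' Convenience wrapper producing one row per requested method. With a
#' single instrument only the Wald ratio is available; the medians require
#' three instruments and Egger more than two, and unavailable methods are
#' skipped with a message.
#'
#' @inheritParams mr_weighted_median
#' @param methods Subset of `c("ivw", "egger", "wmedian", "pwmedian")`.
#' @param penalty_scale Passed to [mr_penalized_weighted_median()].
#' @param n_tests If non-`NULL`, apply [bonferroni_flag()] with this many
#'   tests.
#' @param rescale_binary Rescale estimates to the per-doubling scale when
#'   the instrument set's exposure is binary (default TRUE).
#' @return An `osteomr_mr` tibble with one row per estimate.
#' @export
mr_all <- function(instruments, methods = c("ivw", "egger", "wmedian", "pwmedian"),
                   n_boot = 1000, seed = NULL, penalty_scale = 20,
                   n_tests = NULL, rescale_binary = TRUE, level = 0.95) {
  instruments <- instrument_cols(instruments)
  methods <- match.arg(methods, several.ok = TRUE)
  k <- nrow(instruments)
  rows <- list()
  if (k == 1) {
    rows$wald <- wald_ratio(instruments$bx, instruments$se_bx,
                            instruments$by, instruments$se_by,
                            exposure_type = exposure_type_of(instruments))
  }
  if (k >= 1 && "ivw" %in% methods) rows$ivw <- mr_ivw(instruments, level = level)
  if ("egger" %in% methods) {
    if (k > 2) {
      rows$egger <- mr_egger(instruments, level = level)
    } else {
      inform("Egger regression skipped: needs more than two variants.")
    }
  }
  if ("wmedian" %in% methods && k >= 3) {
    rows$wmedian <- mr_weighted_median(instruments, n_boot, seed, level)
  }
  if ("pwmedian" %in% methods && k >= 3) {
    rows$pwmedian <- mr_penalized_weighted_median(instruments, n_boot, seed,
                                                  penalty_scale, level)
  }
  out <- dplyr::bind_rows(rows)
  if (rescale_binary && exposure_type_of(instruments) == "binary") {
    out <- rescale_binary_exposure(out, level = level)
  }
  if (!is.null(n_tests)) out <- bonferroni_flag(out, n_tests)
  out$exposure <- attr(instruments, "exposure_name") %||% "exposure"
  out$outcome <- attr(instruments, "outcome_name") %||% "outcome"
  structure(out, class = c("osteomr_mr", class(tibble::tibble())))
}
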