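## broom-style tidiers for the fitted-result classes.

#' Tidy MR estimates
#'
#' @param x An `osteomr_mr` tibble (see [mr_ivw()], [mr_all()]).
#' @param ... Unused.
#' @return A tibble with broom-standard columns `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high` (the
#'   interval on the odds-ratio scale).
#' @export
tidy.osteomr_mr <- function(x, ...) {
  tibble::tibble(
    term = x$method,
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$pvalue,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @rdname tidy.osteomr_mr
#' @export
glance.osteomr_mr <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x),
    n_snps = max(x$n_snps),
    exposure_type = x$exposure_type[1]
  )
}

#' Tidy a pooled meta-analysis result
#'
#' @param x An `osteomr_meta` one-row tibble (see [fixed_effects_meta()]).
#' @param ... Unused.
#' @return A broom-style tibble.
#' @export
tidy.osteomr_meta <- function(x, ...) {
  tibble::tibble(
    term = "pooled",
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$pvalue,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @rdname tidy.osteomr_meta
#' @export
glance.osteomr_meta <- function(x, ...) {
  tibble::tibble(q_stat = x$q_stat, i2 = x$i2, k = x$k)
}

#' Tidy an LD score regression fit
#'
#' @param x An `osteomr_ldsc` tibble (see [h2_regression()],
#'   [rg_regression()]).
#' @param ... Unused.
#' @return A broom-style tibble with one row for the slope-derived quantity
#'   and one for the regression intercept.
#' @export
tidy.osteomr_ldsc <- function(x, ...) {
  tibble::tibble(
    term = c(x$quantity, "intercept"),
    estimate = c(x$estimate, x$intercept),
    std.error = c(x$se, x$intercept_se),
    statistic = estimate / std.error,
    p.value = two_sided_p(statistic)
  )
}

#' @rdname tidy.osteomr_ldsc
#' @export
glance.osteomr_ldsc <- function(x, ...) {
  tibble::tibble(quantity = x$quantity, n_blocks = x$n_blocks, m = x$m)
}
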