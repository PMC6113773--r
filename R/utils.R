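## Shared numerical conventions.
##
## The 95% normal quantile is used at full double precision (1.959964...,
## not 1.96) so that interval arithmetic is reproducible to the precision
## at which odds ratios are printed. Likewise the genomic-control
## denominator is the full-precision chi-square(1) median, 0.4549364...

z_quantile <- function(level = 0.95) qnorm((1 + level) / 2)

CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

## Log-odds multiplier converting a binary exposure's causal effect to the
## "per doubling of the odds" scale. Kept at the conventional printed value
## 0.693 rather than ln 2; the difference is below reporting precision.
DOUBLING_CONSTANT <- 0.693

#' Round half away from zero
#'
#' Rounds to the convention used when printing odds ratios in association
#' tables (0.005 rounds to 0.01, -0.005 to -0.01), unlike [round()]'s
#' round-half-even rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(1.045, 2) # 1.05
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

## Derive a reproducible sub-seed (< 2^31) from a master seed and a stream
## label, so the named randomness streams (genotypes, phenotypes, noise, ...)
## can be regenerated independently of one another.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}
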