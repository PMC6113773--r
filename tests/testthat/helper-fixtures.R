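# In-code fixtures shared across test files.

# A small well-formed summary-statistics data frame.
toy_sumstats_df <- function(n = 5, seed = 42) {
  withr::with_seed(seed, {
    # non-palindromic allele pairs so strand flips stay unambiguous
    ea <- sample(c("A", "C"), n, replace = TRUE)
    data.frame(
      snp_id = sprintf("rs%03d", seq_len(n)),
      chrom = "1",
      pos = seq_len(n) * 1000L,
      effect_allele = ea,
      other_allele = ifelse(ea == "A", "G", "T"),
      eaf = runif(n, 0.1, 0.9),
      beta = rnorm(n, 0, 0.05),
      se = runif(n, 0.005, 0.02),
      pvalue = runif(n, 1e-10, 0.9),
      n = 10000L
    )
  })
}

# Valid instrument set with exact by = causal * bx (+ optional intercept).
exact_instruments <- function(bx, causal, intercept = 0, se_by = 0.01,
                              se_bx = 0.01) {
  osteomr:::new_instruments(
    snp_id = sprintf("rs%03d", seq_along(bx)),
    bx = bx, se_bx = se_bx,
    by = intercept + causal * bx, se_by = se_by
  )
}

# A null sumstats table whose z-scores are exact standard-normal quantiles,
# i.e. the empirical chi-square median equals its theoretical value.
null_quantile_sumstats <- function(n = 1001) {
  p_grid <- (seq_len(n) - 0.5) / n
  z <- qnorm(1 - p_grid / 2) # two-sided p -> |z|
  se <- rep(0.01, n)
  sumstats(
    data.frame(
      snp_id = sprintf("rs%04d", seq_len(n)), chrom = "1",
      pos = seq_len(n) * 100L, effect_allele = "A", other_allele = "G",
      eaf = 0.5, beta = z * se, se = se, pvalue = p_grid, n = 1e5
    ),
    quiet = TRUE
  )
}
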