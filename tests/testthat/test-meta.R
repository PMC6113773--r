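test_that("se_from_ci inverts printed odds-ratio intervals", {
  # hand computation: (ln 1.10 - ln 1.06) / (2 * 1.959964)
  expect_equal(se_from_ci(1.08, 1.06, 1.10), 0.009449, tolerance = 1e-4)
  # degenerate interval
  expect_equal(se_from_ci(1.0, 1.0, 1.0), 0)
  # symmetric log-interval oracle: ln(4) / 3.9199
  expect_equal(se_from_ci(2.0, 1.0, 4.0), log(4) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_error(se_from_ci(1.0, 1.1, 1.2), "bounds")
})

test_that("genomic control leaves an exactly-null table unchanged", {
  x <- null_quantile_sumstats(1001)
  y <- genomic_control(x)
  expect_equal(attr(y, "genomic_lambda"), 1.0, tolerance = 1e-12)
  expect_equal(y$se, x$se)
  expect_equal(y$pvalue, x$pvalue)
})

test_that("doubling every chi-square doubles lambda and scales se by sqrt(2)", {
  x <- null_quantile_sumstats(1001)
  inflated <- x
  inflated$beta <- x$beta * sqrt(2) # chi-square doubles
  y <- genomic_control(inflated)
  expect_equal(attr(y, "genomic_lambda"), 2.0, tolerance = 1e-12)
  expect_equal(y$se, x$se * sqrt(2))
  # corrected z equals the pre-inflation z, so p-values return to the null
  expect_equal(y$pvalue, x$pvalue, tolerance = 1e-10)
})

test_that("lambda on simulated null z-scores is close to 1", {
  x <- null_quantile_sumstats(10000)
  withr::local_seed(2024)
  x$beta <- rnorm(nrow(x)) * x$se
  x$pvalue <- 2 * pnorm(-abs(x$beta / x$se))
  y <- genomic_control(x)
  expect_gt(attr(y, "genomic_lambda"), 0.95)
  expect_lt(attr(y, "genomic_lambda"), 1.05)
})

test_that("a single estimate passes through the meta-analysis unchanged", {
  m <- fixed_effects_meta(data.frame(beta = 0.05, se = 0.01))
  expect_equal(m$beta, 0.05)
  expect_equal(m$se, 0.01)
  expect_equal(m$q_stat, 0)
  expect_equal(m$i2, 0)
  expect_equal(m$k, 1L)
  expect_error(fixed_effects_meta(data.frame(beta = numeric(), se = numeric())),
               "at least one")
})

test_that("pooling the printed two-stage cells reproduces combined odds ratios", {
  # rs430727: both stages at OR 1.03
  s1 <- se_from_ci(1.03, 1.02, 1.05)
  s2 <- se_from_ci(1.03, 1.02, 1.04)
  m <- fixed_effects_meta(data.frame(beta = log(c(1.03, 1.03)), se = c(s1, s2)))
  expect_equal(round_half_away(m$or, 2), 1.03)
  # rs2908007: 1.08 + 1.05 pool to 1.06
  s1 <- se_from_ci(1.08, 1.06, 1.10)
  s2 <- se_from_ci(1.05, 1.04, 1.06)
  m <- fixed_effects_meta(data.frame(beta = log(c(1.08, 1.05)), se = c(s1, s2)))
  expect_equal(round_half_away(m$or, 2), 1.06)
})

test_that("pooled precision dominates and the pool is order/split invariant", {
  withr::local_seed(11)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    est <- data.frame(beta = rnorm(k, 0.05, 0.05), se = runif(k, 0.005, 0.05))
    m <- fixed_effects_meta(est)
    # information never decreases
    expect_lte(m$se, min(est$se))
    # order invariance
    perm <- est[sample(k), ]
    expect_equal(fixed_effects_meta(perm)$beta, m$beta, tolerance = 1e-12)
    # associativity: pooling two pooled halves equals pooling everything
    if (k >= 3) {
      split_at <- sample(k - 1, 1)
      a <- fixed_effects_meta(est[1:split_at, , drop = FALSE])
      b <- fixed_effects_meta(est[(split_at + 1):k, , drop = FALSE])
      ab <- fixed_effects_meta(data.frame(beta = c(a$beta, b$beta),
                                          se = c(a$se, b$se)))
      expect_equal(ab$beta, m$beta, tolerance = 1e-12)
      expect_equal(ab$se, m$se, tolerance = 1e-12)
    }
  }
})

test_that("I-squared is zero whenever all input betas are equal", {
  est <- data.frame(beta = rep(0.04, 4), se = c(0.01, 0.02, 0.03, 0.04))
  m <- fixed_effects_meta(est)
  expect_equal(m$q_stat, 0)
  expect_equal(m$i2, 0)
})

test_that("the genome-wide significance filter applies all three gates strictly", {
  meta <- tibble::tibble(
    snp_id = paste0("rs", 1:6),
    pvalue = c(4e-8, 4e-8, 4e-8, 6e-8, 1e-9, 1e-9),
    n_studies = c(5L, 2L, 3L, 5L, 3L, 4L),
    maf = c(0.30, 0.30, 0.005, 0.30, 0.01, 0.20)
  )
  kept <- gws_filter(meta)
  # rs2 fails the strictly-more-than-two-studies gate, rs3 the MAF gate,
  # rs4 the significance gate; rs5 sits exactly at the (inclusive) MAF bound
  expect_equal(kept$snp_id, c("rs1", "rs5", "rs6"))
})

test_that("per-SNP meta-analysis across simulated cohorts pools correctly", {
  a <- sumstats(toy_sumstats_df(6, seed = 1))
  b <- sumstats(toy_sumstats_df(6, seed = 1))
  b$beta <- a$beta + 0.01
  m <- meta_analyse(list(a, b), gc = FALSE)
  expect_equal(nrow(m), 6L)
  i <- match(a$snp_id, m$snp_id)
  w <- 1 / a$se^2
  expected <- (w * a$beta + w * b$beta) / (2 * w)
  expect_equal(m$beta[i], expected, tolerance = 1e-12)
  expect_true(all(m$n_studies == 2L))
})
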