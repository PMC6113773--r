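test_that("the Wald ratio and its delta-method standard error are exact", {
  expect_equal(wald_ratio(1, 0.01, 0.05, 0.01)$beta, 0.05)
  w <- wald_ratio(0.2, 0.01, 0, 0.01)
  expect_equal(w$beta, 0)
  expect_equal(w$se, 0.05)
  # hand delta-method computation
  w2 <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(w2$beta, 0.2)
  expect_equal(w2$se, 0.05)
  # second-order term adds the exposure uncertainty
  w2b <- wald_ratio(0.1, 0.01, 0.02, 0.005, second_order = TRUE)
  expect_equal(w2b$se, sqrt(0.005^2 / 0.01 + 0.02^2 * 0.01^2 / 0.1^4),
               tolerance = 1e-12)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.005), "bx = 0")
})

test_that("IVW reduces to the Wald ratio for a single instrument", {
  h <- osteomr:::new_instruments("rs1", bx = 0.12, se_bx = 0.01,
                                 by = 0.03, se_by = 0.008)
  ivw <- mr_ivw(h)
  wald <- wald_ratio(0.12, 0.01, 0.03, 0.008)
  expect_equal(ivw$beta, wald$beta)
  expect_equal(ivw$se, wald$se)
})

test_that("IVW equals the precision-weighted mean of identical ratios", {
  h <- osteomr:::new_instruments(
    paste0("rs", 1:3), bx = c(0.1, 0.2, 0.3), se_bx = 0.01,
    by = c(0.02, 0.04, 0.06), se_by = 0.01
  )
  m <- mr_ivw(h)
  expect_equal(m$beta, 0.2, tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(sum(c(0.1, 0.2, 0.3)^2 / 0.01^2)),
               tolerance = 1e-12)
})

test_that("IVW is invariant to flipping instrument orientation", {
  withr::local_seed(5)
  h <- osteomr:::new_instruments(
    paste0("rs", 1:8), bx = runif(8, 0.05, 0.2), se_bx = 0.01,
    by = rnorm(8, 0.02, 0.01), se_by = 0.01
  )
  flipped <- h
  i <- c(2, 5, 7)
  flipped$bx[i] <- -h$bx[i]
  flipped$by[i] <- -h$by[i]
  expect_equal(mr_ivw(flipped)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(flipped)$se, mr_ivw(h)$se, tolerance = 1e-12)
})

test_that("Egger recovers exact slope and intercept structure", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  # no pleiotropy: intercept 0, slope c
  h <- exact_instruments(bx, causal = 0.3)
  e <- mr_egger(h)
  expect_equal(e$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-10)
  # pure directional pleiotropy: intercept a, slope c
  h2 <- exact_instruments(bx, causal = 0.3, intercept = 0.02)
  e2 <- mr_egger(h2)
  expect_equal(e2$beta, 0.3, tolerance = 1e-10)
  expect_equal(e2$intercept, 0.02, tolerance = 1e-10)
  # Egger needs more than two variants
  expect_error(mr_egger(exact_instruments(bx[1:2], 0.3)), "more than two")
})

test_that("Egger matches the hand-solved weighted normal equations", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  by <- c(0.030, 0.018, 0.062, 0.055)
  se_by <- c(0.01, 0.02, 0.01, 0.015)
  h <- osteomr:::new_instruments(paste0("rs", 1:4), bx, 0.01, by, se_by)
  e <- mr_egger(h)
  # closed-form 2x2 weighted least squares
  w <- 1 / se_by^2
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  expect_equal(e$beta, (sw * swxy - swx * swy) / det, tolerance = 1e-10)
  expect_equal(e$intercept, (swxx * swy - swx * swxy) / det, tolerance = 1e-10)
  expect_equal(e$se, sqrt(sw / det), tolerance = 1e-10)
  expect_equal(e$intercept_se, sqrt(swxx / det), tolerance = 1e-10)
})

test_that("the weighted median interpolates ratios by cumulative weight midpoints", {
  # degenerate distribution: all ratios equal
  h <- exact_instruments(c(0.1, 0.2, 0.3), causal = 0.25)
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.25, tolerance = 1e-12)
  # hand evaluation of the midpoint-interpolation formula for ratios
  # (1, 2, 3) with normalised weights (0.5, 0.25, 0.25): cumulative
  # midpoints (0.25, 0.625, 0.875), so the estimate at 0.5 is
  # 1 + (0.5 - 0.25) / (0.625 - 0.25) * (2 - 1) = 5/3
  expect_equal(osteomr:::weighted_median_point(c(1, 2, 3), c(0.5, 0.25, 0.25)),
               5 / 3, tolerance = 1e-12)
  expect_error(mr_weighted_median(exact_instruments(c(0.1, 0.2), 0.2), n_boot = 0),
               "three")
})

test_that("the weighted median resists 50% invalid instruments where IVW cannot", {
  truth <- simulation_truth(causal_beta = 0.2, pleiotropy_mean = 0.1,
                            frac_invalid = 0.5, n_exposure = 30000,
                            n_outcome = 50000, seed = 31)
  sim <- simulate_two_sample(truth, 20)
  h <- harmonize(sim$exposure, sim$outcome)
  wm <- mr_weighted_median(h, n_boot = 400, seed = 13)
  ivw <- mr_ivw(h)
  # the median sits within 2 bootstrap se of the truth; IVW is dragged up
  expect_lt(abs(wm$beta - 0.2), 2 * wm$se)
  expect_gt(ivw$beta, 0.2 + 2 * ivw$se)
})

test_that("penalisation leaves homogeneous input untouched and crushes outliers", {
  bx <- seq(0.05, 0.5, length.out = 10)
  h <- exact_instruments(bx, causal = 0.2, se_by = 0.01)
  wm <- mr_weighted_median(h, n_boot = 0)
  pwm <- mr_penalized_weighted_median(h, n_boot = 0)
  expect_equal(pwm$beta, wm$beta, tolerance = 1e-12)
  # one gross outlier among 10 concordant SNPs, placed on the weakest
  # instrument so the IVW reference point barely moves
  h_out <- h
  h_out$by[1] <- h$by[1] + 0.5
  w_pen <- osteomr:::penalized_weights(h_out$bx, h_out$se_bx, h_out$by,
                                       h_out$se_by, penalty_scale = 20)
  w_raw <- h_out$bx^2 / h_out$se_by^2
  expect_lt(w_pen[1] / w_raw[1], 0.01)
  expect_equal(w_pen[2:10] / w_raw[2:10], rep(1, 9), tolerance = 1e-6)
})

test_that("the penalised median is at least as accurate as the plain median
           under a single pleiotropic SNP", {
  # moderate pleiotropy: penalisation needs the IVW reference point to stay
  # roughly centred, so the single invalid SNP is an outlier of a few sigma
  errs <- purrr::map_dfr(1:500, function(s) {
    truth <- simulation_truth(causal_beta = 0.2, pleiotropy_mean = 0.1,
                              frac_invalid = 0.05, n_exposure = 30000,
                              n_outcome = 20000, seed = 5000 + s)
    sim <- simulate_two_sample(truth, 20)
    h <- harmonize(sim$exposure, sim$outcome)
    tibble::tibble(
      wm = mr_weighted_median(h, n_boot = 0)$beta,
      pwm = mr_penalized_weighted_median(h, n_boot = 0)$beta
    )
  })
  expect_lte(abs(mean(errs$pwm) - 0.2), abs(mean(errs$wm) - 0.2))
})

test_that("power calculation: null gives size, huge samples give certainty", {
  expect_equal(mr_power(0.05, 1e5, 0.5, 0.05, target_or = 1), 0.05,
               tolerance = 1e-12)
  expect_equal(mr_power(3.3e-3, 1e9, 0.5, 0.05, target_or = 1.15), 1.0,
               tolerance = 1e-9)
  # direct normal-CDF oracle at the published alpha
  alpha <- 3.3e-3
  ncp <- log(1.15) * sqrt(1e5 * 0.05 * 0.25)
  oracle <- pnorm(ncp - qnorm(1 - alpha / 2)) + pnorm(-ncp - qnorm(1 - alpha / 2))
  expect_equal(mr_power(alpha, 1e5, 0.5, 0.05, 1.15), oracle, tolerance = 1e-6)
})

test_that("Bonferroni flagging uses a strict threshold for 15 tests", {
  res <- osteomr:::new_mr_estimate("ivw", beta = c(1, 1, 1), se = 1, n_snps = 1L)
  res$pvalue <- c(1.5e-68, 0.01, 0.05 / 15)
  flagged <- bonferroni_flag(res, n_tests = 15)
  expect_equal(flagged$significant_after_bonferroni, c(TRUE, FALSE, FALSE))
})

test_that("estimator z-statistics are invariant under the per-doubling rescale", {
  withr::local_seed(17)
  h <- osteomr:::new_instruments(
    paste0("rs", 1:10), bx = runif(10, 0.05, 0.2), se_bx = 0.01,
    by = rnorm(10, 0.03, 0.02), se_by = 0.01,
    exposure_type = "binary"
  )
  for (fit in list(mr_ivw(h), mr_egger(h))) {
    r <- rescale_binary_exposure(fit)
    expect_equal(r$beta / r$se, fit$beta / fit$se, tolerance = 1e-12)
    expect_equal(r$pvalue, fit$pvalue)
  }
})
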