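test_that("instrument gates keep strong common variants only", {
  df <- toy_sumstats_df(10)
  df$pvalue <- c(1e-9, 1e-9, 1e-9, 1e-7, 1e-9, 0.5, 1e-10, 0.04, 1e-12, 1e-6)
  df$eaf <- c(0.30, 0.96, 0.05, 0.30, 0.50, 0.30, 0.07, 0.30, 0.60, 0.30)
  x <- sumstats(df)
  kept <- select_instruments(x)
  # rs002 fails MAF (0.04), rs003 sits exactly at the exclusive 0.05 bound,
  # rs004/006/008/010 fail significance
  expect_equal(kept$snp_id, c("rs001", "rs005", "rs007", "rs009"))
  expect_warning(select_instruments(x, p_threshold = 1e-20), "no SNPs")
})

make_ld <- function(ids, entries = list()) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  for (e in entries) {
    m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- e[[3]]
  }
  m
}

clump_fixture <- function(pvals, ld) {
  ids <- rownames(ld)
  sumstats(data.frame(
    snp_id = ids, chrom = "1", pos = seq_along(ids) * 1000L,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.01, pvalue = pvals, n = 1e4
  ), quiet = TRUE)
}

test_that("clumping keeps everything when all SNPs are independent", {
  ld <- make_ld(paste0("rs", 1:4))
  x <- clump_fixture(c(1e-10, 1e-9, 1e-8, 1e-7), ld)
  expect_equal(greedy_clump(x, ld)$snp_id, paste0("rs", 1:4))
})

test_that("of two linked SNPs only the lower-P one survives", {
  ld <- make_ld(c("rs1", "rs2"), list(list("rs1", "rs2", 0.5)))
  x <- clump_fixture(c(1e-10, 1e-9), ld)
  expect_equal(greedy_clump(x, ld)$snp_id, "rs1")
})

test_that("chained LD resolves by the greedy lowest-P trace", {
  # r2(1,2) = r2(2,3) = 0.6 but r2(1,3) = 0.01: SNP2 is shed, SNP3 returns
  ld <- make_ld(paste0("rs", 1:4), list(
    list("rs1", "rs2", 0.6), list("rs2", "rs3", 0.6), list("rs1", "rs3", 0.01)
  ))
  x <- clump_fixture(c(1e-12, 1e-11, 1e-10, 1e-9), ld)
  expect_equal(greedy_clump(x, ld)$snp_id, c("rs1", "rs3", "rs4"))
})

test_that("the boundary r-squared value is retained (grouping is r2 > threshold)", {
  ld <- make_ld(c("rs1", "rs2"), list(list("rs1", "rs2", 0.05)))
  x <- clump_fixture(c(1e-10, 1e-9), ld)
  expect_equal(greedy_clump(x, ld)$snp_id, c("rs1", "rs2"))
})

test_that("a SNP absent from the LD matrix is a configuration error naming it", {
  ld <- make_ld(c("rs1", "rs2"))
  x <- clump_fixture(c(1e-10, 1e-9, 1e-8), make_ld(paste0("rs", 1:3)))
  expect_error(greedy_clump(x, ld), "rs3")
})

test_that("clump output is maximal and deterministic under p ties", {
  withr::local_seed(99)
  for (rep in 1:25) {
    n <- 8
    ids <- paste0("rs", 1:n)
    r2 <- matrix(runif(n * n, 0, 0.4), n, n)
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    pv <- sample(c(1e-10, 1e-9, 1e-9, 1e-8), n, replace = TRUE)
    x <- clump_fixture(pv, r2)
    kept <- greedy_clump(x, r2)$snp_id
    discarded <- setdiff(ids, kept)
    # maximality: every discarded SNP is linked to some kept SNP
    for (d in discarded) expect_gt(max(r2[d, kept]), 0.05)
    # determinism under ties
    expect_identical(greedy_clump(x, r2)$snp_id, kept)
  }
})

test_that("binary-exposure rescaling moves to the per-doubling scale", {
  est <- osteomr:::new_mr_estimate("ivw", beta = 1.0, se = 0.1, n_snps = 10L,
                                   exposure_type = "binary")
  r <- rescale_binary_exposure(est)
  expect_equal(r$or, exp(0.693), tolerance = 1e-12)
  # null effect is preserved
  est0 <- osteomr:::new_mr_estimate("ivw", beta = 0, se = 0.1, n_snps = 10L,
                                    exposure_type = "binary")
  expect_equal(rescale_binary_exposure(est0)$or, 1.0)
  # hand computation at the published scale
  est2 <- osteomr:::new_mr_estimate("ivw", beta = 0.0143, se = 0.0071,
                                    n_snps = 10L, exposure_type = "binary")
  r2 <- rescale_binary_exposure(est2)
  expect_equal(r2$or, exp(0.0143 * 0.693), tolerance = 1e-6)
  expect_equal(r2$ci_low, exp(0.693 * (0.0143 - qnorm(0.975) * 0.0071)),
               tolerance = 1e-10)
  # z-statistic (hence p) is invariant
  expect_equal(r2$beta / r2$se, est2$beta / est2$se, tolerance = 1e-12)
  expect_equal(r2$pvalue, est2$pvalue)
  # contract: quantitative exposures may not be rescaled
  estq <- osteomr:::new_mr_estimate("ivw", 0.1, 0.01, 5L, "quantitative")
  expect_error(rescale_binary_exposure(estq), "binary")
})

test_that("LD matrices round-trip through their file format", {
  ld <- make_ld(paste0("rs", 1:3), list(list("rs1", "rs2", 0.25)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  expect_equal(read_ld_matrix(path), ld)
})
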