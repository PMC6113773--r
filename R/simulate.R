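## Seeded synthetic-data generators with known ground truth: multi-cohort
## case-control GWAS summary statistics, two-sample MR instrument sets with
## configurable pleiotropy, and polygenic z-score pairs for LD score
## regression. Every generator is a pure function of (parameters, seed):
## all randomness flows from a single master seed through named substreams
## so each module's test bed can be regenerated independently.

#' Ground-truth parameter set for the simulators
#'
#' Collects the generating parameters that downstream recovery tests are
#' scored against: the causal effect of the exposure on the outcome, the
#' direct-effect (horizontal pleiotropy) distribution and the fraction of
#' invalid instruments carrying it, the two traits' heritabilities and
#' genetic correlation, and the sample sizes of the exposure and outcome
#' studies with their overlap.
#'
#' @param causal_beta True causal effect (log-odds of outcome per exposure
#'   unit).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct effects
#'   carried by invalid instruments.
#' @param frac_invalid Fraction of instruments with a direct effect, in
#'   `[0, 1]`.
#' @param h2_1,h2_2 SNP heritabilities of the two traits, in `[0, 1]`.
#' @param rg_true Genetic correlation, in `[-1, 1]`.
#' @param n_exposure,n_outcome,n_shared Sample sizes of the two studies and
#'   their overlap.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A list of class `osteomr_truth`.
#' @export
simulation_truth <- function(causal_beta = 0, pleiotropy_mean = 0,
                             pleiotropy_sd = 0, frac_invalid = 0,
                             h2_1 = 0, h2_2 = 0, rg_true = 0,
                             n_exposure = 32961, n_outcome = 562258,
                             n_shared = 0, seed = 1) {
  stopifnot_scalar(frac_invalid, "frac_invalid", 0, 1)
  stopifnot_scalar(h2_1, "h2_1", 0, 1)
  stopifnot_scalar(h2_2, "h2_2", 0, 1)
  stopifnot_scalar(rg_true, "rg_true", -1, 1)
  stopifnot_scalar(pleiotropy_sd, "pleiotropy_sd", 0)
  stopifnot_scalar(n_exposure, "n_exposure", 1)
  stopifnot_scalar(n_outcome, "n_outcome", 1)
  stopifnot_scalar(n_shared, "n_shared", 0)
  structure(
    list(
      causal_beta = causal_beta, pleiotropy_mean = pleiotropy_mean,
      pleiotropy_sd = pleiotropy_sd, frac_invalid = frac_invalid,
      h2_1 = h2_1, h2_2 = h2_2, rg_true = rg_true,
      n_exposure = n_exposure, n_outcome = n_outcome, n_shared = n_shared,
      seed = as.integer(seed)
    ),
    class = "osteomr_truth"
  )
}

## Cholesky factor of an AR(1) correlation matrix rho^|i-j|, the per-block
## LD structure used by all genotype-level simulators.
ar1_chol <- function(size, rho) chol(ar1_corr(size, rho))

ar1_corr <- function(size, rho) {
  idx <- seq_len(size)
  rho^abs(outer(idx, idx, "-"))
}

#' AR(1) block r-squared matrix
#'
#' Builds the squared-correlation matrix implied by block-diagonal AR(1)
#' linkage disequilibrium: within a block of `block_size` SNPs the signed
#' correlation between SNPs `i` and `j` is `rho^|i-j|`; across blocks it is
#' zero.
#'
#' @param snp_ids SNP identifiers (determine the dimension and dimnames).
#' @param rho Within-block adjacent-SNP correlation.
#' @param block_size SNPs per LD block.
#' @return A named symmetric r-squared matrix suitable for
#'   [greedy_clump()] and [ld_scores()].
#' @export
ar_ld_matrix <- function(snp_ids, rho = 0.8, block_size = 10) {
  n <- length(snp_ids)
  m <- matrix(0, n, n, dimnames = list(snp_ids, snp_ids))
  starts <- seq(1, n, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1, n)
    m[s:e, s:e] <- ar1_corr(e - s + 1, rho)^2
  }
  m
}

snp_labels <- function(n) sprintf("rs%06d", seq_len(n))

## Draw genotype dosages (0/1/2) for n individuals at the SNPs of one LD
## block: two latent Gaussian haplotypes with AR(1) correlation are
## thresholded at the allele frequency.
draw_block_genotypes <- function(n, eaf, chol_factor) {
  k <- length(eaf)
  thr <- qnorm(1 - eaf)
  hap <- function() {
    z <- matrix(rnorm(n * k), n, k) %*% chol_factor
    sweep(z, 2, thr, ">") * 1
  }
  hap() + hap()
}

#' Simulate multi-cohort case-control GWAS summary statistics
#'
#' Emulates the per-cohort output of a fracture-style case-control GWAS:
#' genotypes are drawn from block-diagonal AR(1) LD, case status follows a
#' logistic model with sex, age (linear and quadratic), height and weight
#' covariates plus the specified per-allele SNP effects, and each cohort's
#' per-SNP association is estimated by logistic regression adjusted for the
#' same covariates (additive coding). The logistic intercept is tuned so
#' the expected case count matches `n_cases`; realised counts vary
#' binomially around it. Fits are iteratively reweighted least squares
#' (via [stats::glm.fit()]) capped at 25 iterations with tolerance 1e-8;
#' non-converged SNPs are dropped and counted.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_snps Number of SNPs.
#' @param n_cases,n_controls Expected case and control counts per cohort.
#' @param ld_block_spec List with `block_size` and `rho` for the AR(1) LD
#'   blocks.
#' @param effect_or Named numeric vector of per-allele odds ratios keyed by
#'   SNP id (e.g. `c(rs000001 = 1.10)`); unnamed SNPs are null.
#' @param maf_range Range from which effect-allele frequencies are drawn.
#' @param seed Master seed.
#' @return A list with `tables` (one [sumstats()] per cohort) and `truth`
#'   (the generating parameters, including the realised allele
#'   frequencies and the seed).
#' @export
simulate_cohort_gwas <- function(n_cohorts, n_snps, n_cases, n_controls,
                                 ld_block_spec = list(block_size = 10, rho = 0.8),
                                 effect_or = NULL, maf_range = c(0.05, 0.95),
                                 seed = 1) {
  if (n_cases < 10 || n_controls < 10) {
    abort("at least 10 expected cases and controls per cohort are required.")
  }
  n <- n_cases + n_controls
  prevalence <- n_cases / n
  block_size <- ld_block_spec$block_size %||% 10
  rho <- ld_block_spec$rho %||% 0.8
  ids <- snp_labels(n_snps)
  beta_g <- setNames(rep(0, n_snps), ids)
  if (!is.null(effect_or)) {
    unknown <- setdiff(names(effect_or), ids)
    if (length(unknown) > 0) {
      abort(paste0("effect_or names not among simulated SNPs: ",
                   paste(unknown, collapse = ", ")))
    }
    beta_g[names(effect_or)] <- log(effect_or)
  }

  eaf <- withr::with_seed(sub_seed(seed, "frequencies"),
                          runif(n_snps, maf_range[1], maf_range[2]))
  starts <- seq(1, n_snps, by = block_size)
  chols <- lapply(starts, function(s) {
    ar1_chol(min(s + block_size - 1, n_snps) - s + 1, rho)
  })

  ## covariate effects of the generating disease model (log-odds units)
  b_sex <- 0.3; b_age <- 0.03; b_age2 <- 5e-4; b_height <- -0.01; b_weight <- 0.005

  simulate_one <- function(cohort) {
    geno <- withr::with_seed(sub_seed(seed, paste0("genotypes", cohort)), {
      do.call(cbind, lapply(seq_along(starts), function(bi) {
        s <- starts[bi]; e <- min(s + block_size - 1, n_snps)
        draw_block_genotypes(n, eaf[s:e], chols[[bi]])
      }))
    })
    withr::with_seed(sub_seed(seed, paste0("phenotypes", cohort)), {
      sex <- rbinom(n, 1, 0.5)
      age <- runif(n, 40, 90)
      age_c <- age - 65
      height <- rnorm(n, 168, 9)
      weight <- rnorm(n, 75, 12)
      eta_fixed <- b_sex * sex + b_age * age_c + b_age2 * age_c^2 +
        b_height * (height - 168) + b_weight * (weight - 75) +
        drop(geno %*% beta_g)
      b0 <- stats::uniroot(
        function(b) mean(stats::plogis(b + eta_fixed)) - prevalence,
        interval = c(-20, 20)
      )$root
      case <- rbinom(n, 1, stats::plogis(b0 + eta_fixed))
      if (sum(case) == 0 || sum(case) == n) {
        abort("degenerate cohort: all cases or all controls.")
      }
      covars <- cbind(1, sex, age_c, age_c^2, height - 168, weight - 75)
      fits <- lapply(seq_len(n_snps), function(j) {
        x <- cbind(covars, geno[, j])
        fit <- suppressWarnings(
          stats::glm.fit(x, case, family = stats::binomial(),
                         control = list(epsilon = 1e-8, maxit = 25))
        )
        if (!fit$converged) return(c(NA_real_, NA_real_))
        cov_u <- chol2inv(fit$qr$qr[1:ncol(x), 1:ncol(x), drop = FALSE])
        c(fit$coefficients[ncol(x)], sqrt(diag(cov_u))[ncol(x)])
      })
      est <- do.call(rbind, fits)
      keep <- is.finite(est[, 1]) & is.finite(est[, 2]) & est[, 2] > 0
      sumstats(
        tibble::tibble(
          snp_id = ids[keep], chrom = "1",
          pos = seq_len(n_snps)[keep] * 1000L,
          effect_allele = "A", other_allele = "G",
          eaf = colMeans(geno)[keep] / 2,
          beta = est[keep, 1], se = est[keep, 2],
          pvalue = two_sided_p(est[keep, 1] / est[keep, 2]),
          n = n
        ),
        trait_name = sprintf("fracture_cohort%d", cohort),
        trait_type = "binary", quiet = TRUE
      )
    })
  }

  tables <- lapply(seq_len(n_cohorts), simulate_one)
  list(
    tables = tables,
    truth = list(
      effect_log_or = beta_g, eaf = setNames(eaf, ids),
      n_cohorts = n_cohorts, n_cases = n_cases, n_controls = n_controls,
      ld_block_spec = list(block_size = block_size, rho = rho), seed = seed
    )
  )
}

#' Simulate a two-sample MR instrument set with known causal effect
#'
#' Generates exposure and outcome summary statistics for `n_snps`
#' independent instruments. True instrument strengths `bx` are drawn
#' uniformly from `bx_range` (trait-increasing orientation); outcome
#' effects follow `by = causal_beta * bx + alpha`, where `alpha = 0` for
#' valid instruments and `alpha ~ N(pleiotropy_mean, pleiotropy_sd^2)` for
#' the invalid fraction. The InSIDE condition holds unless `inside_cor`
#' couples `alpha` with instrument strength. Sampling noise is added with
#' standard errors `1/sqrt(n_exposure)` for the (standardised) exposure
#' and `1/sqrt(n_outcome * K (1-K))` for the binary-outcome log-odds,
#' `K = case_fraction`.
#'
#' @param truth A [simulation_truth()].
#' @param n_snps Number of instruments.
#' @param bx_range Range of true instrument effects per allele (exposure SD
#'   units).
#' @param case_fraction Outcome case fraction `K` (default 0.329, a
#'   fracture-scale case-control mix).
#' @param inside_cor Correlation between pleiotropic effects and instrument
#'   strength; non-zero values violate InSIDE.
#' @return A list with `exposure` and `outcome` [sumstats()] tables, `ld`
#'   (identity r-squared matrix: instruments are post-clumping,
#'   independent), and `truth`.
#' @export
simulate_two_sample <- function(truth, n_snps, bx_range = c(0.03, 0.15),
                                case_fraction = 0.329, inside_cor = 0) {
  stopifnot_scalar(inside_cor, "inside_cor", -1, 1)
  ids <- snp_labels(n_snps)
  se_bx <- 1 / sqrt(truth$n_exposure)
  se_by <- 1 / sqrt(truth$n_outcome * case_fraction * (1 - case_fraction))

  out <- withr::with_seed(sub_seed(truth$seed, "two_sample"), {
    eaf <- runif(n_snps, 0.1, 0.9)
    bx_true <- runif(n_snps, bx_range[1], bx_range[2])
    n_invalid <- round(truth$frac_invalid * n_snps)
    invalid <- seq_len(n_snps) %in% sample.int(n_snps, n_invalid)
    eps <- rnorm(n_snps)
    if (inside_cor != 0) {
      bx_std <- as.numeric(scale(bx_true))
      eps <- inside_cor * bx_std + sqrt(1 - inside_cor^2) * eps
    }
    alpha <- ifelse(invalid, truth$pleiotropy_mean + truth$pleiotropy_sd * eps, 0)
    by_true <- truth$causal_beta * bx_true + alpha
    bx_hat <- bx_true + rnorm(n_snps, 0, se_bx)
    by_hat <- by_true + rnorm(n_snps, 0, se_by)
    list(eaf = eaf, bx = bx_hat, by = by_hat, invalid = invalid,
         bx_true = bx_true, alpha = alpha)
  })

  mk <- function(beta, se, trait, type, n) {
    sumstats(
      tibble::tibble(
        snp_id = ids, chrom = "1", pos = seq_len(n_snps) * 1000L,
        effect_allele = "A", other_allele = "G", eaf = out$eaf,
        beta = beta, se = se, pvalue = two_sided_p(beta / se), n = n
      ),
      trait_name = trait, trait_type = type, quiet = TRUE
    )
  }
  ld <- diag(n_snps)
  dimnames(ld) <- list(ids, ids)
  list(
    exposure = mk(out$bx, se_bx, "exposure", "quantitative", truth$n_exposure),
    outcome = mk(out$by, se_by, "outcome", "binary", truth$n_outcome),
    ld = ld,
    truth = c(unclass(truth),
              list(invalid = setNames(out$invalid, ids),
                   bx_true = setNames(out$bx_true, ids),
                   alpha = setNames(out$alpha, ids)))
  )
}

#' Simulate a pair of polygenic GWAS z-score vectors for LDSC
#'
#' Draws per-SNP true effects for two traits from a bivariate normal with
#' variances `h2_i / M` and correlation `rg_true`, propagates them through
#' block-diagonal AR(1) LD (so each z-score tags the signal of its LD
#' partners), and adds unit-variance sampling noise. Overlapping samples
#' induce cross-trait noise correlation
#' `n_shared * rho_pheno / sqrt(n1 n2)` with phenotypic correlation
#' `rho_pheno = rg sqrt(h2_1 h2_2) + env_cor sqrt((1-h2_1)(1-h2_2))`,
#' which LD score regression absorbs into its intercept. Expected
#' chi-square is `1 + N h2 l_j / M`.
#'
#' @param truth A [simulation_truth()] (uses `h2_1`, `h2_2`, `rg_true`,
#'   `n_exposure` as N1, `n_outcome` as N2, `n_shared`, `seed`).
#' @param n_snps Number of SNPs `M`.
#' @param ld_block_spec List with `block_size` and `rho`; a length-2 `rho`
#'   is treated as a range from which each block's correlation is drawn,
#'   giving the spread of LD scores (including near-independent SNPs) that
#'   anchors the regression intercept.
#' @param env_cor Environmental correlation among overlapping samples
#'   (default 0.2).
#' @return A list with `z` (tibble `snp_id`, `z1`, `z2`), `scores`
#'   ([ld_scores()]-compatible), and `truth`.
#' @export
simulate_ldsc_pair <- function(truth, n_snps,
                               ld_block_spec = list(block_size = 50,
                                                    rho = c(0.1, 0.95)),
                               env_cor = 0.2) {
  block_size <- ld_block_spec$block_size %||% 50
  rho <- ld_block_spec$rho %||% c(0.1, 0.95)
  ids <- snp_labels(n_snps)
  n1 <- truth$n_exposure; n2 <- truth$n_outcome
  h1 <- truth$h2_1; h2 <- truth$h2_2; rg <- truth$rg_true

  rho_pheno <- rg * sqrt(h1 * h2) + env_cor * sqrt((1 - h1) * (1 - h2))
  noise_cor <- truth$n_shared * rho_pheno / sqrt(n1 * n2)

  starts <- seq(1, n_snps, by = block_size)
  z <- withr::with_seed(sub_seed(truth$seed, "ldsc"), {
    block_rho <- if (length(rho) == 2) {
      runif(length(starts), rho[1], rho[2])
    } else {
      rep(rho, length(starts))
    }
    ## true effects: bivariate normal, correlation rg
    e1 <- rnorm(n_snps); e2 <- rnorm(n_snps)
    b1 <- sqrt(h1 / n_snps) * e1
    b2 <- sqrt(h2 / n_snps) * (rg * e1 + sqrt(1 - rg^2) * e2)
    ## sampling noise, correlated across traits through sample overlap
    u1 <- rnorm(n_snps); u2 <- rnorm(n_snps)
    eps1 <- u1
    eps2 <- noise_cor * u1 + sqrt(1 - noise_cor^2) * u2
    sig1 <- numeric(n_snps); sig2 <- numeric(n_snps); ell <- numeric(n_snps)
    for (bi in seq_along(starts)) {
      s <- starts[bi]
      e <- min(s + block_size - 1, n_snps)
      r_mat <- ar1_corr(e - s + 1, block_rho[bi])
      sig1[s:e] <- drop(r_mat %*% b1[s:e])
      sig2[s:e] <- drop(r_mat %*% b2[s:e])
      ell[s:e] <- rowSums(r_mat^2)
    }
    list(z1 = sqrt(n1) * sig1 + eps1, z2 = sqrt(n2) * sig2 + eps2, ell = ell)
  })

  list(
    z = tibble::tibble(snp_id = ids, z1 = z$z1, z2 = z$z2),
    scores = new_ld_scores(ids, z$ell, n_snps),
    truth = unclass(truth)
  )
}
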