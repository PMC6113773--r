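## Packaged reference tables: stage-level estimates for the 15 genome-wide
## significant fracture loci, the stage case/control totals, and the
## published MR estimates for the 15 clinical risk factors. All are small
## tab-delimited transcriptions shipped under extdata/.

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "osteomr")
  if (path == "") abort(sprintf("packaged fixture %s not found.", file))
  path
}

read_fixture <- function(file) {
  readr::read_tsv(fixture_path(file), comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = "NA")
}

#' Packaged fracture GWAS reference tables
#'
#' `fracture_loci()` returns the per-locus discovery, replication and
#' combined odds ratios (with 95% CIs and p-values) for the 15 genome-wide
#' significant fracture loci; `fracture_stage_counts()` the case/control
#' totals of each stage; `fracture_mr_estimates()` the published MR
#' estimates (IVW odds ratio, Egger intercept, power) for the 15 clinical
#' risk factors.
#'
#' @return A tibble.
#' @export
fracture_loci <- function() read_fixture("fracture_loci_stages.tsv")

#' @rdname fracture_loci
#' @export
fracture_stage_counts <- function() read_fixture("fracture_stage_counts.tsv")

#' @rdname fracture_loci
#' @export
fracture_mr_estimates <- function() read_fixture("fracture_mr_estimates.tsv")

## SE of the log-odds ratio for one printed stage cell, preferring the
## confidence interval and falling back to the p-value when the printed
## interval is internally inconsistent (degenerate, or excluding the point
## estimate — occasional typesetting artefacts in published tables).
stage_se <- function(or, lo, hi, p, level = 0.95) {
  consistent <- is.finite(lo) & is.finite(hi) &
    lo > 0 & lo < or & or < hi
  ifelse(consistent,
         (log(hi) - log(lo)) / (2 * z_quantile(level)),
         se_from_p(or, p))
}

#' Pool printed stage estimates into combined odds ratios
#'
#' Rebuilds the combined estimate of each locus from its printed
#' discovery and replication cells: per-stage log-odds standard errors are
#' recovered with [se_from_ci()] (falling back to [se_from_p()] for cells
#' whose printed interval is internally inconsistent) and pooled with
#' [fixed_effects_meta()].
#'
#' @param loci A table shaped like [fracture_loci()].
#' @return `loci` with columns `or_pooled`, `se_pooled`, `pvalue_pooled`,
#'   `i2_pooled` appended, plus `or_pooled_2dp` (rounded half away from
#'   zero to the 2 decimals at which combined odds ratios are printed).
#' @export
pool_printed_stages <- function(loci) {
  pooled <- purrr::pmap_dfr(loci, function(or_disc, ci_low_disc, ci_high_disc,
                                           p_disc, or_rep, ci_low_rep,
                                           ci_high_rep, p_rep, ...) {
    stages <- data.frame(
      beta = c(log(or_disc), log(or_rep)),
      se = c(stage_se(or_disc, ci_low_disc, ci_high_disc, p_disc),
             stage_se(or_rep, ci_low_rep, ci_high_rep, p_rep))
    )
    m <- fixed_effects_meta(stages)
    tibble::tibble(or_pooled = m$or, se_pooled = m$se,
                   pvalue_pooled = m$pvalue, i2_pooled = m$i2)
  })
  dplyr::bind_cols(loci, pooled) |>
    dplyr::mutate(or_pooled_2dp = round_half_away(.data$or_pooled, 2))
}
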