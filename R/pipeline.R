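#' Run the full qPCR validation analysis
#'
#' Convenience wrapper chaining the validation stages: Pfaffl
#' efficiency-corrected relative quantification with a multi-reference
#' normalization factor, log2 transformation, extreme-outlier screening
#' (Q3 + k*IQR) with exclusion of the flagged samples, per-gene Student
#' t-tests with BH-FDR, and the two-way ANOVA adjusting the malignancy
#' contrast for the oncocytic feature (its own BH family). The combined
#' per-gene table mirrors the layout of a validation summary: fold change
#' (FTC/FTA), FDR-corrected t-test p and FDR-corrected ANOVA p.
#'
#' @param data a [qpcr_dataset()].
#' @param annot a [sample_annotation()].
#' @param calibrator passed to [pfaffl_relative_quantity()].
#' @param outlier_k IQR multiplier for the exclusion rule, default 6.
#' @param exclude_outliers drop samples flagged by the outlier rule before
#'   testing (default `TRUE`).
#' @param run_anova set `FALSE` to skip the oncocytic adjustment (e.g. when
#'   the flag is constant).
#' @return List with `normalized` (linear [expression_matrix()]), `log2`
#'   (after exclusion), `outliers` (an `outlier_report`), `de` (t-test
#'   [ttest_fdr()] table), `anova` (or `NULL`) and `table` (merged summary).
#' @export
run_qpcr_validation <- function(data, annot, calibrator = "mean",
                                outlier_k = 6, exclude_outliers = TRUE,
                                run_anova = TRUE) {
  norm <- pfaffl_relative_quantity(data, calibrator = calibrator)
  lg <- log_transform(norm)
  rep_out <- flag_extreme_outliers(lg, k = outlier_k)
  keep <- colnames(lg$values)
  if (exclude_outliers && length(rep_out$excluded_samples))
    keep <- setdiff(keep, rep_out$excluded_samples)
  lg_used <- lg
  lg_used$values <- lg$values[, keep, drop = FALSE]
  annot_used <- annot[annot$sample_id %in% keep, , drop = FALSE]
  de <- ttest_fdr(lg_used, annot_used)
  av <- if (run_anova) anova_adjusted(lg_used, annot_used) else NULL
  tab <- de[, c("gene", "fold_change", "t_p", "t_q")]
  if (!is.null(av)) {
    tab$anova_p <- av$anova_p[match(tab$gene, av$gene)]
    tab$anova_q <- av$anova_q[match(tab$gene, av$gene)]
  }
  list(normalized = norm, log2 = lg_used, outliers = rep_out, de = de,
       anova = av, table = tab)
}
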