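#' Flag extreme expression outliers by the Q3 + k*IQR rule
#'
#' For every gene, the first and third quartiles (linear-interpolation
#' quantiles) are computed over all samples and cells strictly exceeding
#' `Q3 + k * IQR` are flagged. A sample is listed in `excluded_samples` when
#' it is flagged in at least `min_genes` genes. The report is advisory: the
#' caller decides whether to drop the listed samples. With the default
#' multiplier k = 6 the rule only reacts to gross, assay-level artefacts, not
#' to ordinary biological spread.
#'
#' @param matrix an [expression_matrix()] (any scale).
#' @param k non-negative IQR multiplier, default 6.
#' @param min_genes minimum number of flagged genes for a sample to be listed
#'   for exclusion, default 1.
#' @return An object of class `outlier_report`: list with `flags` (data frame
#'   of sample/gene/value/threshold), `excluded_samples`, and `per_gene`
#'   (Q1, Q3, IQR and threshold per gene).
#' @export
flag_extreme_outliers <- function(matrix, k = 6, min_genes = 1) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (k < 0) stop("'k' must be non-negative")
  v <- matrix$values
  if (ncol(v) < 4) stop("need at least 4 samples to estimate quartiles")
  q1 <- apply(v, 1, stats::quantile, probs = 0.25, type = 7)
  q3 <- apply(v, 1, stats::quantile, probs = 0.75, type = 7)
  iqr <- q3 - q1
  thr <- q3 + k * iqr
  hits <- which(v > thr, arr.ind = TRUE)   # thr recycles down columns
  flags <- data.frame(sample = colnames(v)[hits[, 2]],
                      gene = rownames(v)[hits[, 1]],
                      value = v[hits],
                      threshold = thr[hits[, 1]],
                      stringsAsFactors = FALSE)
  flags <- flags[order(flags$sample, flags$gene), , drop = FALSE]
  rownames(flags) <- NULL
  tab <- table(flags$sample)
  structure(list(flags = flags,
                 excluded_samples = sort(names(tab)[tab >= min_genes]),
                 per_gene = data.frame(gene = rownames(v), q1 = q1, q3 = q3,
                                       iqr = iqr, threshold = thr,
                                       row.names = NULL),
                 k = k, min_genes = min_genes),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report (Q3 + %g*IQR): %d flagged cell(s), %d sample(s) marked for exclusion\n",
              x$k, nrow(x$flags), length(x$excluded_samples)))
  if (length(x$excluded_samples))
    cat("  excluded:", paste(x$excluded_samples, collapse = ", "), "\n")
  invisible(x)
}

# Vectorized per-row two-sample t-test on a log2 matrix.
# Returns t statistic, p value and the class means; equal-variance (classical
# Student) by default, Welch optional.
row_ttest <- function(v, idx1, idx2, var_equal = TRUE) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- v[, idx1, drop = FALSE]; x2 <- v[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  if (var_equal) {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0        # degenerate: identical constant groups
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se == 0 & m1 == m2] <- 1
  list(t = t, p = p, mean1 = m1, mean2 = m2, df = df)
}

#' Per-gene two-group differential expression with BH-FDR
#'
#' Classical (equal-variance) Student's t-test of FTC versus FTA per gene on
#' log2 values; the linear fold change is `2^(mean_FTC - mean_FTA)`.
#' Benjamini-Hochberg step-up adjustment is applied across all tested genes.
#' Genes with any missing value (e.g. assays that failed to amplify) are
#' dropped before testing and reported in the `dropped_genes` attribute, not
#' imputed.
#'
#' @param matrix a log2-scale [expression_matrix()], or a plain numeric
#'   matrix of log2 values.
#' @param annot a [sample_annotation()] covering the matrix columns.
#' @param var_equal classical Student t (default) or Welch when `FALSE`.
#' @return A data frame of class `de_result` with one row per gene: class
#'   means, `fold_change` (linear FTC/FTA), `overall_mean`, `overall_var`,
#'   `t_stat`, `t_p` (raw) and `t_q` (BH-adjusted), plus `n_ftc`/`n_fta`.
#' @export
ttest_fdr <- function(matrix, annot, var_equal = TRUE) {
  v <- if (inherits(matrix, "expr_matrix")) {
    if (matrix$scale != "log2")
      stop("ttest_fdr expects log2-scale values; call log_transform() first")
    matrix$values
  } else matrix
  annot <- annot[match(colnames(v), annot$sample_id), , drop = FALSE]
  if (anyNA(annot$sample_id))
    stop("annotation missing for samples: ",
         paste(setdiff(colnames(v), annot$sample_id), collapse = ", "))
  idx_ftc <- which(annot$diagnosis == "FTC")
  idx_fta <- which(annot$diagnosis == "FTA")
  if (length(idx_ftc) < 2 || length(idx_fta) < 2)
    stop("each class needs at least 2 samples (FTC: ", length(idx_ftc),
         ", FTA: ", length(idx_fta), ")")
  dropped <- rownames(v)[apply(v, 1, anyNA)]
  if (length(dropped)) v <- v[!rownames(v) %in% dropped, , drop = FALSE]
  tt <- row_ttest(v, idx_ftc, idx_fta, var_equal = var_equal)
  out <- data.frame(gene = rownames(v),
                    n_ftc = length(idx_ftc), n_fta = length(idx_fta),
                    mean_ftc = tt$mean1, mean_fta = tt$mean2,
                    fold_change = 2^(tt$mean1 - tt$mean2),
                    overall_mean = rowMeans(v),
                    overall_var = apply(v, 1, stats::var),
                    t_stat = tt$t, t_p = tt$p,
                    t_q = stats::p.adjust(tt$p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped_genes") <- dropped
  class(out) <- c("de_result", "data.frame")
  out
}

#' Two-way ANOVA adjusting the malignancy contrast for the oncocytic feature
#'
#' Per gene, an additive two-factor linear model
#' `log2 expression ~ oncocytic + diagnosis` is fitted and the
#' malignancy-factor p-value is taken from Type II sums of squares (each
#' factor tested after adjusting for the other; for an additive model this is
#' the `drop1` partial F-test). BH adjustment is applied across genes, as its
#' own family separate from the t-test family.
#'
#' @inheritParams ttest_fdr
#' @return Data frame with per-gene `anova_F`, `anova_p` (raw) and `anova_q`
#'   (BH-adjusted) for the malignancy factor.
#' @export
anova_adjusted <- function(matrix, annot) {
  v <- if (inherits(matrix, "expr_matrix")) {
    if (matrix$scale != "log2")
      stop("anova_adjusted expects log2-scale values")
    matrix$values
  } else matrix
  annot <- annot[match(colnames(v), annot$sample_id), , drop = FALSE]
  diagnosis <- factor(annot$diagnosis)
  oncocytic <- factor(annot$oncocytic)
  if (nlevels(diagnosis) < 2) stop("degenerate design: only one diagnosis level")
  if (nlevels(oncocytic) < 2) stop("degenerate design: oncocytic flag is constant")
  # aliased when the oncocytic flag is constant within every diagnosis level
  if (all(tapply(oncocytic, diagnosis, function(z) length(unique(z))) == 1))
    stop("confounded design: diagnosis and oncocytic factor are aliased")
  res <- t(apply(v, 1, function(y) {
    fit <- stats::lm(y ~ oncocytic + diagnosis)
    d1 <- stats::drop1(fit, test = "F")
    c(F = d1["diagnosis", "F value"], p = d1["diagnosis", "Pr(>F)"])
  }))
  out <- data.frame(gene = rownames(v), anova_F = res[, 1], anova_p = res[, 2],
                    anova_q = stats::p.adjust(res[, 2], method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Two-set marker filter for microarray candidate selection
#'
#' Retains genes that, in the primary (high-confidence) dataset, have
#' normalized mean expression above `min_mean`, per-gene variance above the
#' `var_percentile` quantile of all gene variances, raw Student-t p below
#' `max_p`, and a fold change of at least `min_fc` in either direction
#' (FC >= min_fc or FC <= 1/min_fc) — and that additionally reach raw p below
#' `secondary_max_p` in the secondary dataset.
#'
#' @param primary_de [ttest_fdr()] result on the primary dataset (must carry
#'   `overall_mean` and `overall_var`).
#' @param secondary_de [ttest_fdr()] result on the secondary dataset over the
#'   same gene universe.
#' @param min_mean,var_percentile,max_p,min_fc,secondary_max_p filter
#'   thresholds; defaults are the published criteria (4.5, 0.20, 0.001, 1.5,
#'   0.05).
#' @return Character vector of retained genes, ordered by primary raw p.
#' @export
two_set_marker_filter <- function(primary_de, secondary_de,
                                  min_mean = 4.5, var_percentile = 0.20,
                                  max_p = 0.001, min_fc = 1.5,
                                  secondary_max_p = 0.05) {
  if (!setequal(primary_de$gene, secondary_de$gene)) {
    d1 <- setdiff(primary_de$gene, secondary_de$gene)
    d2 <- setdiff(secondary_de$gene, primary_de$gene)
    stop("gene universes differ; only in primary: ",
         paste(utils::head(d1, 5), collapse = ", "),
         "; only in secondary: ", paste(utils::head(d2, 5), collapse = ", "))
  }
  var_cut <- stats::quantile(primary_de$overall_var, var_percentile, type = 7)
  keep <- primary_de$overall_mean > min_mean &
    primary_de$overall_var > var_cut &
    primary_de$t_p < max_p &
    (primary_de$fold_change >= min_fc | primary_de$fold_change <= 1 / min_fc)
  sec_p <- secondary_de$t_p[match(primary_de$gene, secondary_de$gene)]
  keep <- keep & sec_p < secondary_max_p
  genes <- primary_de$gene[keep]
  genes[order(primary_de$t_p[keep])]
}

#' Project samples onto the first two principal components
#'
#' Genes (rows) of the requested subset are mean-centred and the samples are
#' projected onto the first two principal components. The sign of each
#' component is fixed so that the gene with the largest absolute loading has
#' a positive loading, making scores reproducible across platforms.
#'
#' @param matrix an [expression_matrix()] (log2 scale recommended).
#' @param gene_subset character vector (>= 2 genes) present in the matrix.
#' @return List with `scores` (samples x 2), `loadings` (genes x 2) and
#'   `explained` (fraction of variance of the first two components).
#' @export
pca_project <- function(matrix, gene_subset) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (length(gene_subset) < 2)
    stop("'gene_subset' must contain at least 2 genes")
  missing <- setdiff(gene_subset, rownames(matrix$values))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  x <- t(matrix$values[gene_subset, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(scores = scores, loadings = loadings, explained = expl)
}
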