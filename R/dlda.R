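#' Select genes by raw t-test p-value
#'
#' Genes whose classical Student t-test p-value falls below `alpha` are
#' retained. If no gene passes, the single smallest-p gene is returned and
#' the `fallback` attribute is set, so a classifier always has at least one
#' feature.
#'
#' @param matrix log2 gene-by-sample matrix (or [expression_matrix()]).
#' @param labels factor/character of class labels (`"FTC"`/`"FTA"`) per column.
#' @param alpha significance threshold in (0, 1].
#' @return Character vector of selected genes, attribute `fallback` logical.
#' @export
select_genes_ttest <- function(matrix, labels, alpha) {
  v <- if (inherits(matrix, "expr_matrix")) matrix$values else matrix
  labels <- as.character(labels)
  idx1 <- which(labels == "FTC"); idx2 <- which(labels == "FTA")
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("both classes need at least 2 samples")
  p <- row_ttest(v, idx1, idx2)$p
  sel <- rownames(v)[p < alpha]
  fallback <- FALSE
  if (length(sel) == 0) {
    sel <- rownames(v)[which.min(p)]
    fallback <- TRUE
  }
  attr(sel, "fallback") <- fallback
  sel
}

#' Train a diagonal linear discriminant analysis (DLDA) model
#'
#' DLDA is a Gaussian classifier with class-specific per-gene means and a
#' shared diagonal covariance: the pooled within-class variance per gene,
#' denominator n - 2. Variances are floored at `1e-8 *` the median pooled
#' variance to avoid degeneracy on (near-)constant genes. Class priors are
#' the empirical class proportions by default, or equal.
#'
#' @param matrix log2 gene-by-sample matrix (rows = the features to use).
#' @param labels class labels per column (`"FTC"`/`"FTA"`).
#' @param priors `"empirical"` or `"equal"`.
#' @param alpha_used optional record of the selection threshold that produced
#'   the feature set.
#' @return An object of class `dlda_model`.
#' @export
dlda_train <- function(matrix, labels, priors = c("empirical", "equal"),
                       alpha_used = NA_real_) {
  priors <- match.arg(priors)
  v <- if (inherits(matrix, "expr_matrix")) matrix$values else matrix
  labels <- as.character(labels)
  classes <- c("FTA", "FTC")
  if (!all(labels %in% classes)) stop("labels must be FTC or FTA")
  n1 <- sum(labels == "FTA"); n2 <- sum(labels == "FTC")
  if (n1 == 0 || n2 == 0)
    stop("single-class input: both FTC and FTA must be present")
  if (n1 + n2 < 3) stop("need at least 3 samples to pool a variance")
  x1 <- v[, labels == "FTA", drop = FALSE]
  x2 <- v[, labels == "FTC", drop = FALSE]
  mu <- cbind(FTA = rowMeans(x1), FTC = rowMeans(x2))
  ss <- rowSums((x1 - mu[, "FTA"])^2) + rowSums((x2 - mu[, "FTC"])^2)
  s2 <- ss / (n1 + n2 - 2)
  floor_at <- 1e-8 * stats::median(s2)
  s2 <- pmax(s2, floor_at)
  if (any(s2 <= 0)) s2 <- pmax(s2, 1e-12)  # all-constant pathological input
  pi_ <- if (priors == "empirical") c(FTA = n1, FTC = n2) / (n1 + n2)
         else c(FTA = 0.5, FTC = 0.5)
  structure(list(selected_genes = rownames(v), means = mu, variances = s2,
                 priors = pi_, alpha_used = alpha_used),
            class = "dlda_model")
}

#' Posterior FTC probability under a DLDA model
#'
#' \eqn{P(\mathrm{FTC}\mid x) = \pi_{FTC} \prod_g N(x_g; \mu_{FTC,g},
#' \sigma^2_g) / \sum_c \pi_c \prod_g N(x_g; \mu_{c,g}, \sigma^2_g)},
#' evaluated in log space for numerical stability.
#'
#' @param model a [dlda_train()] model.
#' @param x named numeric vector covering `model$selected_genes`, or a
#'   gene-by-sample matrix (one probability per column).
#' @return Numeric FTC probability (vector for matrix input).
#' @export
dlda_posterior <- function(model, x) {
  stopifnot(inherits(model, "dlda_model"))
  g <- model$selected_genes
  if (is.matrix(x)) {
    if (!all(g %in% rownames(x)))
      stop("sample is missing genes: ",
           paste(setdiff(g, rownames(x)), collapse = ", "))
    xm <- x[g, , drop = FALSE]
  } else {
    if (!all(g %in% names(x)))
      stop("sample is missing genes: ",
           paste(setdiff(g, names(x)), collapse = ", "))
    xm <- matrix(x[g], ncol = 1, dimnames = list(g, NULL))
  }
  s2 <- model$variances
  ll <- function(cls) {
    colSums(stats::dnorm(xm, mean = model$means[, cls], sd = sqrt(s2),
                         log = TRUE)) + log(model$priors[cls])
  }
  d <- ll("FTA") - ll("FTC")
  p <- 1 / (1 + exp(d))
  if (is.matrix(x)) p else unname(p)
}
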